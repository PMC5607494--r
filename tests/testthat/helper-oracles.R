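# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (brute force / enumeration) and never call
# the code paths they check.

small_config <- function(seed = 42L, n_chrom = 2L, chrom_length = 150000L,
                         n_hmds = 12L, ...) {
  synthetic_config(seed = seed, n_chrom = n_chrom,
                   chrom_length = chrom_length, n_hmds = n_hmds, ...)
}

# cache: one small dataset reused across test files
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_synthetic(small_config())
    ds
  }
})

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# naive sliding-window k-mer counter (oracle for kmer_features)
naive_kmer_counts <- function(seq, k) {
  kms <- substring(seq, seq_len(nchar(seq) - k + 1L),
                   seq_len(nchar(seq) - k + 1L) + k - 1L)
  all_k <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                      1, paste0, collapse = ""))
  tab <- table(factor(kms, levels = all_k))
  setNames(as.numeric(tab), all_k)
}

# brute-force HMD scanner: enumerate maximal runs by walking the records
brute_hmds <- function(meth, min_cpgs = 10L, thr = 0.4) {
  out <- list()
  for (ch in unique(meth$chrom)) {
    d <- meth[meth$chrom == ch, ]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_cpgs)
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch, start = d$pos[run[1]],
          end = d$pos[run[length(run)]] + 2L, n_cpgs = length(run))
    }
    for (i in seq_len(nrow(d))) {
      if (d$ratio[i] < thr) run <- c(run, i)
      else { flush(run); run <- integer(0) }
    }
    flush(run)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer())
}

# direct O(n^2) lag-by-lag Pearson autocorrelation (textbook formula,
# independent of stats::cor)
brute_acf <- function(x, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(k) {
    a <- x[seq_len(n - k)]; b <- x[(k + 1L):n]
    ac <- a - sum(a) / length(a); bc <- b - sum(b) / length(b)
    sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  }, numeric(1))
}

# exhaustive hard-rod partition: enumerate every non-overlapping rod set
brute_occupancy <- function(E, L, m, z) {
  sets <- list(integer(0))
  for (s in seq_len(L - m + 1L)) {
    add <- lapply(Filter(function(cfg)
      all(abs(cfg - s) >= m), sets), function(cfg) c(cfg, s))
    sets <- c(sets, add)
  }
  w <- vapply(sets, function(cfg) prod(z * exp(-E[cfg])), numeric(1))
  Z <- sum(w)
  occ <- numeric(L)
  for (i in seq_along(sets)) {
    for (s in sets[[i]]) occ[s:(s + m - 1L)] <- occ[s:(s + m - 1L)] + w[i]
  }
  list(occupancy = occ / Z, Z = Z)
}

# minimal hmd_set builder for unit tests that do not need real CpG runs
make_hmds <- function(chrom, start, end) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   n_cpgs = rep(10L, length(start)),
                   boundary_cpg_5p = start,
                   boundary_cpg_3p = end - 2L,
                   cpg_positions = I(lapply(start, function(s) s)),
                   hmd_id = seq_along(start))
  class(df) <- c("hmd_set", "data.frame")
  df
}

flat_track <- function(lens, value = 0) {
  signal_track(lapply(lens, function(l) rep(value, l)))
}
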