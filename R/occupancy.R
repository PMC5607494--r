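## Equilibrium nucleosome occupancy under the 1-D hard-rod model: rods of a
## fixed footprint (147 bp) bind non-overlappingly with sequence-dependent
## Boltzmann factors z * exp(-E(i)); forward/backward partial partition
## sums give exact per-start placement probabilities and per-base
## occupancy. All arithmetic is in log space so chromosome-scale inputs do
## not overflow.

#' GC-content binding-energy model
#'
#' `E(i) = -weight * GC(window)`: with positive weight, GC-rich footprints
#' bind more tightly (the classic global nucleosome preference); a negative
#' weight inverts the preference.
#'
#' @param weight energy units per unit GC fraction.
#' @param footprint rod length in bp.
#' @return Object of class `energy_model`.
#' @export
gc_energy_model <- function(weight = 1, footprint = 147L) {
  force(weight); force(footprint)
  new_energy_model(footprint, function(seq) {
    L <- nchar(seq)
    gc <- cumsum(strsplit(seq, "")[[1]] %in% c("G", "C"))
    win <- (gc[footprint:L] - c(0, gc[seq_len(L - footprint)])) / footprint
    -weight * win
  }, tag = paste0("gc:", weight))
}

#' Tabulated binding-energy model
#'
#' Reads a TSV of per-k-mer energies (columns kmer, energy); the energy of a
#' rod is the mean energy of the k-mers it covers (k inferred from the
#' table). Useful for loading published or fitted parameters.
#'
#' @param path TSV path with columns kmer, energy.
#' @param footprint rod length in bp.
#' @return Object of class `energy_model`.
#' @export
tabulated_energy_model <- function(path, footprint = 147L) {
  tb <- data.table::fread(path, header = TRUE)
  if (!all(c("kmer", "energy") %in% names(tb))) stop("malformed energy table")
  k <- unique(nchar(tb$kmer))
  if (length(k) != 1) stop("k-mers of mixed length in energy table")
  e <- setNames(tb$energy, tb$kmer)
  if (anyNA(e) || any(!is.finite(e))) stop("non-finite energies in table")
  new_energy_model(footprint, function(seq) {
    L <- nchar(seq)
    kms <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    ek <- e[kms]
    if (anyNA(ek)) stop("sequence k-mer missing from energy table")
    cs <- cumsum(c(0, unname(ek)))
    nwin <- footprint - k + 1L
    (cs[(nwin + 1L):(L - k + 2L)] - cs[seq_len(L - footprint + 1L)]) / nwin
  }, tag = paste0("table:", basename(path)))
}

#' Construct an energy model from a function
#'
#' @param footprint rod length in bp (>= 1).
#' @param energy_fun function(seq) returning one energy per valid rod start
#'   (length `nchar(seq) - footprint + 1`); lower = tighter binding.
#' @param tag provenance label.
#' @return Object of class `energy_model`.
#' @export
new_energy_model <- function(footprint, energy_fun, tag = "custom") {
  if (footprint < 1) stop("footprint must be >= 1")
  structure(list(footprint = as.integer(footprint), energy = energy_fun,
                 tag = tag), class = "energy_model")
}

log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
logaddexp <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

#' Expected nucleosome occupancy of a sequence
#'
#' Exact equilibrium statistics of non-overlapping rods: forward partition
#' sums `F[i]` over the first `i` bases, backward sums `R[i]`, per-start
#' placement probability
#' `P[i] = F[i-1] * z * exp(-E[i]) * R[i+footprint] / Z`, and per-base
#' occupancy as the sum of placement probabilities of rods covering the
#' base. Rods must lie fully inside the sequence.
#'
#' @param seq ACGT(N) string with `nchar(seq) >= footprint`.
#' @param model an `energy_model`.
#' @param fugacity rod concentration parameter z (> 0); higher values pack
#'   more rods.
#' @return List of class `occupancy_profile`: occupancy (per base, in
#'   `[0,1]`), p_start (per valid start), log_partition.
#' @export
nucleosome_occupancy <- function(seq, model, fugacity = 1.0) {
  if (fugacity <= 0) stop("fugacity must be > 0")
  m <- model$footprint
  L <- nchar(seq)
  if (L < m) stop("sequence shorter than footprint")
  E <- model$energy(seq)
  ns <- L - m + 1L
  if (length(E) != ns) stop("energy model returned wrong length")
  logz <- log(fugacity)
  lw <- logz - E  # log statistical weight of a rod at each start
  # logF[i+1] = log partition of prefix of length i (i = 0..L)
  logF <- numeric(L + 1L)
  for (i in seq_len(L)) {
    f <- logF[i]  # no rod ends at i
    if (i >= m) f <- logaddexp(f, logF[i - m + 1L] + lw[i - m + 1L])
    logF[i + 1L] <- f
  }
  logR <- numeric(L + 1L)  # logR[i+1] = log partition of suffix starting after i
  for (i in rev(seq_len(L))) {
    r <- logR[i + 1L]
    if (i + m - 1L <= L) r <- logaddexp(r, logR[i + m] + lw[i])
    logR[i] <- r
  }
  logZ <- logF[L + 1L]
  p_start <- exp(logF[seq_len(ns)] + lw + logR[(seq_len(ns)) + m] - logZ)
  occ <- cumsum(c(p_start, numeric(m - 1L))) -
    cumsum(c(numeric(m), p_start[seq_len(L - m)]))
  occ <- pmin(pmax(occ[seq_len(L)], 0), 1)
  structure(list(occupancy = occ, p_start = p_start, log_partition = logZ,
                 fugacity = fugacity, footprint = m, tag = model$tag),
            class = "occupancy_profile")
}

#' Occupancy signal track over a genome
#'
#' Runs [nucleosome_occupancy()] per chromosome and returns a
#' `signal_track` (useful for metaprofiles around boundary anchors).
#'
#' @param genome a `genome_sequence`.
#' @param model an `energy_model`.
#' @param fugacity rod concentration parameter.
#' @return A `signal_track`.
#' @export
occupancy_track <- function(genome, model, fugacity = 1.0) {
  vals <- lapply(names(genome), function(ch)
    nucleosome_occupancy(genome[[ch]], model, fugacity)$occupancy)
  signal_track(setNames(vals, names(genome)))
}
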