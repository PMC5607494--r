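## Periodicity of high-weight k-mers inside HMDs: pooled occurrence
## positions per HMD and the histogram of all within-HMD pairwise distances.

#' Reverse a k-mer (no complementation)
#'
#' The reversed sequence keeps the base composition but destroys the base
#' ordering, serving as a composition-matched control motif.
#'
#' @param kmer ACGT string.
#' @return The reversed string.
#' @export
reverse_kmer <- function(kmer) {
  if (any(grepl("[^ACGT]", kmer))) stop("k-mer must contain only ACGT")
  vapply(strsplit(kmer, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Occurrence positions of a k-mer list inside HMDs
#'
#' Scans the forward strand of each HMD sequence for every k-mer in the list
#' (overlapping matches included) and pools the match start positions per
#' HMD.
#'
#' @param genome a `genome_sequence`.
#' @param hmds an `hmd_set`.
#' @param kmers character vector of ACGT k-mers (e.g. top 10 by SVM weight).
#' @return Object of class `motif_occurrences`: list with `kmers` and
#'   `positions`, a per-HMD list of sorted absolute start positions.
#' @export
kmer_occurrences <- function(genome, hmds, kmers) {
  if (any(grepl("[^ACGT]", kmers))) stop("k-mers must contain only ACGT")
  pos <- vector("list", nrow(hmds))
  for (i in seq_len(nrow(hmds))) {
    s <- Biostrings::DNAString(
      get_sequence(genome, hmds$chrom[i], hmds$start[i], hmds$end[i]))
    hits <- integer(0)
    for (km in kmers) {
      m <- Biostrings::matchPattern(km, s)
      if (length(m)) hits <- c(hits, Biostrings::start(m) - 1L + hmds$start[i])
    }
    pos[[i]] <- sort(hits)
  }
  structure(list(kmers = kmers, positions = pos,
                 hmd_id = hmds$hmd_id), class = "motif_occurrences")
}

#' Histogram of within-HMD pairwise distances between motif occurrences
#'
#' All unordered pairs of pooled occurrence positions within the same HMD
#' (cross-HMD pairs never form). Distances below `min_dist` (self-overlap
#' artifacts) or above `max_dist` are excluded.
#'
#' @param occ a `motif_occurrences` object.
#' @param min_dist exclusive lower distance bound in bp.
#' @param max_dist inclusive upper distance bound in bp.
#' @param binwidth histogram bin width in bp.
#' @return List of class `distance_histogram`: bin_start, bin_end, count,
#'   mode_bin_center, n_pairs.
#' @export
pairwise_distance_histogram <- function(occ, min_dist = 3L, max_dist = 1000L,
                                        binwidth = 10L) {
  if (binwidth <= 0) stop("binwidth must be > 0")
  dists <- unlist(lapply(occ$positions, function(p) {
    if (length(p) < 2) return(integer(0))
    abs(unlist(lapply(seq_along(p), function(i) p[-seq_len(i)] - p[i])))
  }), use.names = FALSE)
  dists <- dists[dists >= min_dist & dists <= max_dist]
  edges <- seq(min_dist, max_dist + binwidth, by = binwidth)
  counts <- as.integer(table(cut(dists, edges, right = FALSE,
                                 include.lowest = FALSE)))
  bin_start <- head(edges, -1)
  bin_end <- edges[-1]
  mode_center <- if (length(dists)) {
    i <- which.max(counts)
    (bin_start[i] + bin_end[i]) / 2
  } else NA_real_
  structure(list(bin_start = bin_start, bin_end = bin_end, count = counts,
                 mode_bin_center = mode_center, n_pairs = length(dists),
                 min_dist = min_dist, max_dist = max_dist,
                 binwidth = binwidth),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("<distance_histogram> ", x$n_pairs, " pairs in (", x$min_dist, ", ",
      x$max_dist, "], bin ", x$binwidth, " bp; mode at ",
      x$mode_bin_center, " bp\n", sep = "")
  invisible(x)
}
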