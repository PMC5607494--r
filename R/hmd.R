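## Hypomethylated domain (HMD) calling: maximal runs of consecutive
## low-methylated CpGs along the genome.

#' Call hypomethylated domains from per-CpG methylation ratios
#'
#' An HMD is a maximal run of at least `min_cpgs` consecutive CpGs (in genome
#' order) whose methylation ratio is strictly below `ratio_threshold`. The
#' domain interval spans from the first to the last CpG of the run; the end is
#' `last pos + 2` so the final CpG dinucleotide is covered. CpGs missing from
#' the input (e.g. no coverage) neither break nor extend runs; setting
#' `max_gap` makes runs break when consecutive low CpGs are further apart
#' than `max_gap` bp.
#'
#' @param meth data.frame with chrom, pos (0-based C of the CpG), ratio,
#'   sorted by (chrom, pos), one record per CpG.
#' @param min_cpgs minimum number of consecutive low-methylated CpGs.
#' @param ratio_threshold CpGs with ratio strictly below this count as
#'   low-methylated.
#' @param max_gap optional maximum distance (bp) between consecutive CpGs of
#'   a run; `Inf` (default) applies no distance cap.
#' @return `data.frame` of class `hmd_set`: chrom, start, end, n_cpgs,
#'   boundary_cpg_5p, boundary_cpg_3p, hmd_id, and a list column
#'   `cpg_positions` with the member CpG positions.
#' @export
call_hmds <- function(meth, min_cpgs = 10L, ratio_threshold = 0.4,
                      max_gap = Inf) {
  stopifnot(all(c("chrom", "pos", "ratio") %in% names(meth)))
  if (any(meth$ratio < 0 | meth$ratio > 1)) stop("ratio outside [0,1]")
  o <- order(meth$chrom, meth$pos)
  if (!identical(o, seq_len(nrow(meth)))) stop("methylation records not sorted")
  out <- list()
  for (ch in unique(meth$chrom)) {
    pos <- meth$pos[meth$chrom == ch]
    low <- meth$ratio[meth$chrom == ch] < ratio_threshold
    if (is.finite(max_gap) && length(pos) > 1) {
      # split runs that jump more than max_gap
      gapbreak <- c(FALSE, diff(pos) > max_gap)
      grp <- cumsum((!low) | gapbreak)
    } else {
      grp <- cumsum(!low)
    }
    for (g in split(which(low), grp[low])) {
      if (length(g) >= min_cpgs) {
        p <- pos[g]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = p[1], end = p[length(p)] + 2L,
          n_cpgs = length(p), boundary_cpg_5p = p[1],
          boundary_cpg_3p = p[length(p)],
          cpg_positions = I(list(p)))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), boundary_cpg_5p = integer(),
               boundary_cpg_3p = integer(),
               cpg_positions = I(list()))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res$hmd_id <- seq_len(nrow(res))
  class(res) <- c("hmd_set", "data.frame")
  res
}

#' Fraction of the genome covered by HMDs
#'
#' @param hmds an `hmd_set` (or any chrom/start/end data.frame) with
#'   non-overlapping intervals.
#' @param genome a `genome_sequence` (or named vector of chromosome lengths).
#' @return Total HMD bp divided by total genome bp.
#' @export
genome_fraction <- function(hmds, genome) {
  lens <- if (inherits(genome, "genome_sequence")) chrom_lengths(genome)
          else genome
  for (ch in unique(hmds$chrom)) {
    h <- hmds[hmds$chrom == ch, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    if (nrow(h) > 1 && any(h$start[-1] < h$end[-nrow(h)]))
      stop("overlapping HMDs on ", ch)
  }
  sum(hmds$end - hmds$start) / sum(lens)
}
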