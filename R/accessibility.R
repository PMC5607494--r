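## Accessibility: cut-position shifting, smoothed coverage, and a
## deterministic local-maxima summit caller used as a lightweight stand-in
## for a full peak caller. Externally called summits (narrowPeak) are
## accepted anywhere summits are consumed.

#' Shift cut positions toward the 5' side of the read
#'
#' Plus-strand cuts move upstream (`pos - shift`), minus-strand cuts move
#' downstream (`pos + shift`); set `toward_five_prime = FALSE` for the
#' opposite sign convention. Positions are clipped to chromosome bounds.
#'
#' @param cuts data.frame with chrom, pos (0-based 5' end), strand (`+`/`-`).
#' @param shift shift magnitude in bp.
#' @param chrom_lengths named vector of chromosome lengths for clipping.
#' @param toward_five_prime shift direction convention.
#' @return data.frame of shifted cuts.
#' @export
shift_cuts <- function(cuts, shift = 50L, chrom_lengths = NULL,
                       toward_five_prime = TRUE) {
  if (!all(cuts$strand %in% c("+", "-"))) stop("unknown strand value")
  sgn <- ifelse(cuts$strand == "+", -1L, 1L)
  if (!toward_five_prime) sgn <- -sgn
  pos <- cuts$pos + sgn * as.integer(shift)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[cuts$chrom] - 1L
    pos <- pmax(0L, pmin(pos, lim))
  } else {
    pos <- pmax(0L, pos)
  }
  out <- cuts
  out$pos <- as.integer(pos)
  out
}

#' Per-base cut coverage, smoothed and scaled to counts per million
#'
#' Counts cuts per base, convolves with a boxcar (moving average) of width
#' `smooth_bw`, and scales to counts per million cuts. The boxcar conserves
#' total mass away from chromosome edges.
#'
#' @param cuts data.frame with chrom, pos.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param smooth_bw boxcar width in bp (0 disables smoothing); default 73 bp,
#'   half a nucleosome footprint.
#' @param per_million scale to counts per million cuts.
#' @return A `signal_track`.
#' @export
cut_coverage <- function(cuts, chrom_lengths, smooth_bw = 73L,
                         per_million = TRUE) {
  if (nrow(cuts) == 0) stop("empty cut list")
  if (smooth_bw < 0) stop("smooth_bw must be >= 0")
  scale <- if (per_million) 1e6 / nrow(cuts) else 1
  vals <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    v <- numeric(len)
    p <- cuts$pos[cuts$chrom == ch]
    if (length(p)) {
      tb <- tabulate(p + 1L, nbins = len)
      v <- tb * scale
      if (smooth_bw > 1) {
        k <- rep(1 / smooth_bw, smooth_bw)
        v <- as.numeric(stats::filter(v, k, sides = 2))
        v[is.na(v)] <- 0  # edge effect of the centered filter
      }
    }
    vals[[ch]] <- v
  }
  signal_track(vals)
}

#' Call summits as greedy local maxima of a signal track
#'
#' Candidate positions are local maxima with height at least `min_height`
#' and at least `fold_enrichment` times the global median of the nonzero
#' signal. Candidates are selected greedily by decreasing height with an
#' exclusion radius of `min_separation` bp; ties break toward the leftmost
#' position.
#'
#' @param track a `signal_track`.
#' @param min_height absolute minimum summit height.
#' @param min_separation exclusion radius in bp (>= 1).
#' @param fold_enrichment required fold over the global nonzero median.
#' @return data.frame: chrom, pos, height, sorted by (chrom, pos).
#' @export
call_summits <- function(track, min_height = 0, min_separation = 150L,
                         fold_enrichment = 5) {
  if (min_separation < 1) stop("min_separation must be >= 1")
  allv <- unlist(track$values, use.names = FALSE)
  nz <- allv[!is.na(allv) & allv > 0]
  floor_h <- max(min_height, if (length(nz)) fold_enrichment * median(nz) else 0)
  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    v0 <- ifelse(is.na(v), -Inf, v)
    n <- length(v0)
    if (n < 3) next
    mid <- v0[2:(n - 1)]
    # plateau-tolerant local maxima: strictly above left, >= right
    cand <- which(mid > v0[1:(n - 2)] & mid >= v0[3:n]) + 1L
    cand <- cand[v0[cand] >= floor_h]
    if (!length(cand)) next
    o <- order(-v0[cand], cand)
    cand <- cand[o]
    taken <- integer(0)
    for (p in cand) {
      if (!length(taken) || all(abs(taken - p) >= min_separation))
        taken <- c(taken, p)
    }
    out[[ch]] <- data.frame(chrom = ch, pos = sort(taken) - 1L,
                            height = v0[sort(taken)])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), height = numeric())
  rownames(res) <- NULL
  res
}

#' Overlap statistics between summits and HMDs
#'
#' @param summits data.frame with chrom, pos.
#' @param hmds an `hmd_set` (chrom, start, end).
#' @param genome a `genome_sequence` or named vector of chromosome lengths.
#' @return List: `frac_hmds_with_dhs` (fraction of HMDs containing at least
#'   one summit), `frac_dhs_in_hmd` (fraction of summits inside an HMD),
#'   `frac_genome_hmd` (fraction of the genome covered by HMDs).
#' @export
overlap_stats <- function(summits, hmds, genome) {
  in_hmd <- summit_in_hmd(summits, hmds)
  has <- rep(FALSE, nrow(hmds))
  has[unique(in_hmd$hmd_idx)] <- TRUE
  list(frac_hmds_with_dhs = if (nrow(hmds)) mean(has) else 0,
       frac_dhs_in_hmd = if (nrow(summits)) nrow(in_hmd) / nrow(summits) else 0,
       frac_genome_hmd = genome_fraction(hmds, genome))
}

# map each summit to the HMD containing it (if any); returns summit_idx, hmd_idx
summit_in_hmd <- function(summits, hmds) {
  if (!nrow(summits) || !nrow(hmds))
    return(data.frame(summit_idx = integer(), hmd_idx = integer()))
  qs <- IRanges::IRanges(summits$pos + 1L, summits$pos + 1L)
  ss <- IRanges::IRanges(hmds$start + 1L, hmds$end)
  hit <- IRanges::findOverlaps(qs, ss)
  ok <- summits$chrom[S4Vectors::queryHits(hit)] ==
    hmds$chrom[S4Vectors::subjectHits(hit)]
  data.frame(summit_idx = S4Vectors::queryHits(hit)[ok],
             hmd_idx = S4Vectors::subjectHits(hit)[ok])
}
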