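## Boundary anchors and anchor-aligned average profiles (metaprofiles).
##
## Each HMD boundary is anchored at the in-HMD summit nearest the boundary
## CpG, and labelled 5' or 3' by the direction of transcription of the
## nearest TSS: if transcription runs from the methylated flank into the HMD
## at that boundary, the boundary is 5'. Profiles are aligned so that the
## methylated flank sits at negative offsets and the HMD interior at
## positive offsets for both boundary classes.

#' Select boundary anchors for metaprofiles
#'
#' Only HMDs with a TSS within `max_tss_dist` bp of the domain are used.
#' For each end of each such HMD that contains at least one summit, the
#' in-HMD summit nearest the boundary CpG becomes the anchor. The TSS
#' nearest the anchor (ties broken toward the HMD interior) orients the
#' boundary: 5' when it transcribes from the methylated side into the HMD,
#' 3' otherwise.
#'
#' @param hmds an `hmd_set`.
#' @param summits data.frame with chrom, pos.
#' @param tss data.frame with chrom, start, end, strand ("+"/"-"); the TSS
#'   position is `start`.
#' @param max_tss_dist maximum HMD-to-TSS distance in bp.
#' @return data.frame of class `boundary_anchors`: chrom, pos, side
#'   (`"5p"`/`"3p"`), orientation (strand of the nearest TSS), interior
#'   (`"+"` if the HMD interior lies at higher coordinates), hmd_id.
#' @export
select_anchors <- function(hmds, summits, tss, max_tss_dist = 1000L) {
  stopifnot(all(c("chrom", "start", "strand") %in% names(tss)))
  out <- list()
  for (i in seq_len(nrow(hmds))) {
    ch <- hmds$chrom[i]
    sp <- summits$pos[summits$chrom == ch &
                      summits$pos >= hmds$start[i] & summits$pos < hmds$end[i]]
    if (!length(sp)) next
    tp <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(tp)) next
    # HMD-level filter: a TSS must lie within max_tss_dist of the domain
    d_hmd <- pmax(hmds$start[i] - tp$start, tp$start - (hmds$end[i] - 1L), 0L)
    if (min(d_hmd) > max_tss_dist) next
    for (which_end in c("left", "right")) {
      bnd <- if (which_end == "left") hmds$boundary_cpg_5p[i] else
        hmds$boundary_cpg_3p[i]
      anchor <- sp[which.min(abs(sp - bnd))]
      interior <- if (which_end == "left") "+" else "-"
      d <- abs(tp$start - anchor)
      # ties toward the HMD interior
      into <- if (which_end == "left") tp$start >= anchor else tp$start <= anchor
      o <- order(d, !into)
      tstrand <- tp$strand[o[1]]
      side <- if (tstrand == interior) "5p" else "3p"
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = anchor, side = side, orientation = tstrand,
        interior = interior, hmd_id = hmds$hmd_id[i])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), side = character(),
               orientation = character(), interior = character(),
               hmd_id = integer())
  rownames(res) <- NULL
  class(res) <- c("boundary_anchors", "data.frame")
  res
}

#' Anchor-aligned average profile of a signal track
#'
#' Extracts a `[-flank, +flank]` window around each anchor and averages the
#' track per offset. With `orient = TRUE`, windows whose HMD interior lies at
#' lower coordinates (`interior == "-"`) are reversed, so positive offsets
#' always point into the HMD. Undefined track positions (and positions
#' beyond chromosome ends) are excluded from both the numerator and the
#' per-offset count `n`.
#'
#' @param track a `signal_track`.
#' @param anchors a `boundary_anchors` data.frame (or any chrom/pos frame;
#'   an `interior` column is required when `orient = TRUE`).
#' @param flank half-window in bp.
#' @param orient flip windows so the HMD interior is at positive offsets.
#' @return data.frame of class `metaprofile`: offset, mean, n.
#' @export
metaprofile <- function(track, anchors, flank = 1000L, orient = TRUE) {
  if (!nrow(anchors)) stop("no anchors")
  if (flank <= 0) stop("flank must be > 0")
  w <- 2L * flank + 1L
  acc <- numeric(w)
  cnt <- integer(w)
  for (i in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[i]]]
    if (is.null(v)) next
    idx <- (anchors$pos[i] - flank):(anchors$pos[i] + flank) + 1L
    ok <- idx >= 1L & idx <= length(v)
    win <- rep(NA_real_, w)
    win[ok] <- v[idx[ok]]
    if (orient && anchors$interior[i] == "-") win <- rev(win)
    def <- !is.na(win)
    acc[def] <- acc[def] + win[def]
    cnt <- cnt + def
  }
  res <- data.frame(offset = -flank:flank,
                    mean = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
                    n = cnt)
  class(res) <- c("metaprofile", "data.frame")
  res
}

#' Per-base k-mer occurrence track
#'
#' Marks the start of every forward-strand match of `kmer` with 1 (0
#' elsewhere). Overlapping matches are all counted.
#'
#' @param genome a `genome_sequence`.
#' @param kmer ACGT string.
#' @return A `signal_track`.
#' @export
kmer_occurrence_track <- function(genome, kmer) {
  if (grepl("[^ACGT]", kmer)) stop("k-mer must contain only ACGT")
  vals <- list()
  for (ch in names(genome)) {
    v <- numeric(nchar(genome[[ch]]))
    m <- Biostrings::matchPattern(kmer, Biostrings::DNAString(genome[[ch]]))
    st <- Biostrings::start(m)
    if (length(st)) v[st] <- v[st] + 1
    vals[[ch]] <- v
  }
  signal_track(vals)
}

#' Sliding-bin SNP rate track
#'
#' SNP indicator per base smoothed with a centered boxcar of width
#' `binsize`, i.e. SNPs per bp in a sliding window.
#'
#' @param snps data.frame with chrom, pos.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param binsize sliding window width in bp.
#' @return A `signal_track`.
#' @export
snp_rate_track <- function(snps, chrom_lengths, binsize = 100L) {
  if (binsize <= 0) stop("binsize must be > 0")
  vals <- list()
  for (ch in names(chrom_lengths)) {
    v <- numeric(chrom_lengths[[ch]])
    p <- snps$pos[snps$chrom == ch]
    if (length(p)) v <- tabulate(p + 1L, nbins = length(v))
    sm <- as.numeric(stats::filter(v, rep(1 / binsize, binsize), sides = 2))
    sm[is.na(sm)] <- 0
    vals[[ch]] <- sm
  }
  signal_track(vals)
}

#' Per-base count track from point positions (TSSs, dyads)
#'
#' @param positions data.frame with chrom and pos (or start, for BED-style
#'   point features).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param smooth_bw optional boxcar width in bp (0 = raw counts).
#' @return A `signal_track`.
#' @export
count_track <- function(positions, chrom_lengths, smooth_bw = 0L) {
  pcol <- if ("pos" %in% names(positions)) positions$pos else positions$start
  vals <- list()
  for (ch in names(chrom_lengths)) {
    v <- numeric(chrom_lengths[[ch]])
    p <- pcol[positions$chrom == ch]
    if (length(p)) v <- as.numeric(tabulate(p + 1L, nbins = length(v)))
    if (smooth_bw > 1) {
      v <- as.numeric(stats::filter(v, rep(1 / smooth_bw, smooth_bw), sides = 2))
      v[is.na(v)] <- 0
    }
    vals[[ch]] <- v
  }
  signal_track(vals)
}
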