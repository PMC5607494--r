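## Domain containers and readers/writers for the standard formats the
## pipeline touches. All coordinates are 0-based half-open throughout the
## package; conversion to/from 1-based formats happens only here.

#' Construct a genome sequence object
#'
#' A genome is a named character vector of uppercase sequences over
#' `{A,C,G,T,N}`. Any letter outside `ACGT` is mapped to `N`.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return An object of class `genome_sequence`.
#' @export
genome_sequence <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names")
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) gsub("[^ACGT]", "N", s), character(1))
  structure(seqs, class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x), " sequence(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_sequence`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Extract a subsequence by 0-based half-open interval
#'
#' @param genome a `genome_sequence`.
#' @param chrom sequence name.
#' @param start,end 0-based half-open coordinates.
#' @return Character string of length `end - start`.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (any(start < 0) || any(end > nchar(genome[[chrom]])) || any(start >= end))
    stop("interval out of bounds")
  substring(genome[[chrom]], start + 1L, end)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and non-ACGT letters mapped to N.
#'
#' @param path FASTA file path.
#' @return A `genome_sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  genome_sequence(setNames(as.character(ss), nm))
}

#' Write a FASTA file
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a per-base signal track
#'
#' Dense per-base numeric values per chromosome; `NA` marks positions where
#' the track is undefined (distinct from signal 0). Undefined positions are
#' excluded from averages downstream, never imputed.
#'
#' @param values named list: chromosome -> numeric vector.
#' @return Object of class `signal_track`.
#' @export
signal_track <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  bad <- vapply(values, function(v) any(is.infinite(v)), logical(1))
  if (any(bad)) stop("non-finite (infinite) track values")
  structure(list(values = lapply(values, as.numeric)), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  n <- sum(lengths(x$values))
  d <- sum(vapply(x$values, function(v) sum(!is.na(v)), numeric(1)))
  cat("<signal_track> ", length(x$values), " chromosome(s), ",
      format(n, big.mark = ","), " bp, ", round(100 * d / max(n, 1), 1),
      "% defined\n", sep = "")
  invisible(x)
}

#' Read a bedGraph file into a dense signal track
#'
#' Intervals must be non-overlapping per chromosome; gaps are undefined
#' (`NA`), not zero.
#'
#' @param path bedGraph path.
#' @param chrom_lengths named vector of chromosome lengths; inferred from the
#'   maximum end coordinate per chromosome when `NULL`.
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  if (any(df$start < 0)) stop("negative coordinates in ", path)
  vals <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", ch)
    len <- if (is.null(chrom_lengths)) max(d$end) else chrom_lengths[[ch]]
    v <- rep(NA_real_, len)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    vals[[ch]] <- v
  }
  signal_track(vals)
}

#' Write a signal track as bedGraph
#'
#' Adjacent runs of equal value are merged (canonical form); undefined
#' positions are omitted. Output is ordered by chromosome then start.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  out <- list()
  for (ch in sort(names(track$values))) {
    v <- track$values[[ch]]
    def <- !is.na(v)
    if (!any(def)) next
    # run-length encode over (defined, value) pairs
    key <- ifelse(def, paste0("v", format(v, digits = 17)), "NA")
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    out[[ch]] <- data.table::data.table(
      chrom = ch, start = starts[keep], end = ends[keep],
      value = v[starts[keep] + 1L])
  }
  dt <- data.table::rbindlist(out)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read intervals from BED or narrowPeak
#'
#' Returns 0-based half-open intervals. For narrowPeak, the absolute summit
#' (`start + column 10`) is added as a `summit` column. Strand is preserved
#' when present.
#'
#' @param path file path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `data.frame` with columns chrom, start, end and, when available,
#'   name, score, strand, summit.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (format == "narrowPeak" && ncol(dt) != 10)
    stop("narrowPeak requires 10 columns, got ", ncol(dt))
  if (format == "bed" && ncol(dt) < 3)
    stop("BED requires >= 3 columns, got ", ncol(dt))
  out <- data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  if (any(out$start < 0)) stop("negative coordinates in ", path)
  if (any(out$start >= out$end)) stop("empty or inverted interval in ", path)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- dt[[5]]
  if (ncol(dt) >= 6) out$strand <- as.character(dt[[6]])
  if (format == "narrowPeak") out$summit <- out$start + as.integer(dt[[10]])
  out
}

#' Write intervals as BED
#'
#' Emits chrom, start, end plus any of name, score, strand present, in
#' deterministic order (chromosome lexicographic, then start).
#'
#' @param intervals data.frame with chrom, start, end.
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED truncation: can't skip a column in the middle
  want <- c("chrom", "start", "end", "name", "score", "strand")
  cols <- want[seq_len(max(which(want %in% cols)))]
  dt <- data.table::as.data.table(intervals)
  for (cc in setdiff(cols, names(dt)))
    dt[[cc]] <- if (cc == "name") "." else if (cc == "score") 0 else "."
  dt <- dt[order(dt$chrom, dt$start), cols, with = FALSE]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-CpG methylation ratios
#'
#' TSV with columns chrom, pos (0-based position of the C of the CpG), ratio
#' in `[0, 1]`.
#'
#' @param path TSV path.
#' @return `data.frame` sorted by (chrom, pos).
#' @export
read_methylation <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "ratio"))
  if (any(dt$ratio < 0 | dt$ratio > 1)) stop("methylation ratio outside [0,1]")
  as.data.frame(dt[order(dt$chrom, dt$pos)])
}

#' Write per-CpG methylation ratios
#' @param meth data.frame with chrom, pos, ratio.
#' @param path output path.
#' @export
write_methylation <- function(meth, path) {
  dt <- data.table::as.data.table(meth[, c("chrom", "pos", "ratio")])
  dt <- dt[order(dt$chrom, dt$pos)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Total overlap in bp between two interval sets
#'
#' @param a,b data.frames with chrom, start, end (0-based half-open).
#' @return Number of base pairs covered by both sets.
#' @export
overlap_bp <- function(a, b) {
  tot <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == ch] + 1L,
                                           a$end[a$chrom == ch]))
    ib <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == ch] + 1L,
                                           b$end[b$chrom == ch]))
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  tot
}
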