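## Synthetic chromatin generator: a toy genome plus every input track the
## pipeline consumes, with ground truth for parameter recovery.
##
## The stated world: a mostly methylated genome carrying hypomethylated
## domains (HMDs) of dense low-ratio CpGs; phased nucleosome arrays with
## 180-bp spacing outside and 200-bp spacing inside HMDs; an extra-wide
## (250 bp) linker at the 5' HMD boundary carrying the TSS; linker-enriched
## planted 6-mers at linker centers inside HMDs only; GC-rich linker
## sequence (the compositional contrast the accessibility SVM can learn
## beyond the planted motifs); accessibility cuts at HMD linkers only plus
## sparse background; dyad-peaked nucleosome reads genome-wide; reduced SNP
## density in HMD linkers.

#' Synthetic dataset configuration
#'
#' Defaults describe the default 5-Mb / 200-HMD world used throughout the
#' test-suite and acceptance runs.
#'
#' @param seed master RNG seed; every track flows from it.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param n_hmds total HMD count (split evenly across chromosomes).
#' @param hmd_length_range uniform HMD length range (bp).
#' @param cpg_spacing_bg,cpg_spacing_hmd CpG grid spacing outside/inside
#'   HMDs (bp).
#' @param meth_beta_hmd,meth_beta_bg Beta(shape1, shape2) of per-CpG
#'   methylation ratios inside HMDs (mean 0.1) and outside (mean 0.85).
#' @param spacing_hmd,spacing_meth nucleosome spacing inside/outside HMDs
#'   (bp; must exceed the 147-bp footprint).
#' @param boundary_gap_5p distance from the 5'-boundary linker to the next
#'   linker (bp) — the NDR at the TSS.
#' @param linker_motifs 6-mers planted at linker centers.
#' @param motif_plant_prob probability a linker center receives a motif.
#' @param dyad_jitter_sd sd (bp) of dyad read positions around true dyads.
#' @param cuts_per_linker Poisson mean of accessibility cuts per linker.
#' @param cut_jitter_sd sd (bp) of cut positions around linker centers.
#' @param background_cut_rate background cuts per bp genome-wide.
#' @param reads_per_dyad Poisson mean of dyad reads per nucleosome.
#' @param background_gc,linker_gc GC fraction of background sequence and of
#'   linker regions inside HMDs.
#' @param linker_halfwidth half-width (bp) of the linker region used for GC
#'   elevation and SNP depletion.
#' @param snp_rate_core,snp_rate_linker per-bp SNP rates outside/inside HMD
#'   linkers.
#' @param tss_at_5p place one TSS at each 5' boundary linker.
#' @param phased_flank extent (bp) of boundary-phased nucleosomes on the
#'   methylated side.
#' @param holdout_chrom chromosome reserved for testing (default: last).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_chrom = 4L, chrom_length = 1.25e6,
                             n_hmds = 200L, hmd_length_range = c(1000L, 3000L),
                             cpg_spacing_bg = 50L, cpg_spacing_hmd = 25L,
                             meth_beta_hmd = c(2, 18),
                             meth_beta_bg = c(8.5, 1.5),
                             spacing_hmd = 200L, spacing_meth = 180L,
                             boundary_gap_5p = 250L,
                             linker_motifs = c("GCTAAC", "CTAGCA", "GATCCG",
                                               "TCATGC", "AGGCTA"),
                             motif_plant_prob = 0.8, dyad_jitter_sd = 15,
                             cuts_per_linker = 40, cut_jitter_sd = 20,
                             background_cut_rate = 1 / 500,
                             reads_per_dyad = 20,
                             background_gc = 0.5, linker_gc = 0.65,
                             linker_halfwidth = 30L,
                             snp_rate_core = 0.01, snp_rate_linker = 0.002,
                             tss_at_5p = TRUE, phased_flank = 1000L,
                             holdout_chrom = NULL) {
  if (spacing_hmd <= 147 || spacing_meth <= 147)
    stop("nucleosome spacing must exceed the 147-bp footprint")
  if (motif_plant_prob < 0 || motif_plant_prob > 1)
    stop("motif_plant_prob must be in [0,1]")
  if (any(grepl("[^ACGT]", linker_motifs))) stop("motifs must be ACGT")
  chroms <- paste0("chr", seq_len(n_chrom))
  if (is.null(holdout_chrom)) holdout_chrom <- chroms[n_chrom]
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              chroms = chroms, n_hmds = as.integer(n_hmds),
              hmd_length_range = as.integer(hmd_length_range),
              cpg_spacing_bg = cpg_spacing_bg,
              cpg_spacing_hmd = cpg_spacing_hmd,
              meth_beta_hmd = meth_beta_hmd, meth_beta_bg = meth_beta_bg,
              spacing_hmd = as.integer(spacing_hmd),
              spacing_meth = as.integer(spacing_meth),
              boundary_gap_5p = as.integer(boundary_gap_5p),
              linker_motifs = linker_motifs,
              motif_plant_prob = motif_plant_prob,
              dyad_jitter_sd = dyad_jitter_sd,
              cuts_per_linker = cuts_per_linker,
              cut_jitter_sd = cut_jitter_sd,
              background_cut_rate = background_cut_rate,
              reads_per_dyad = reads_per_dyad,
              background_gc = background_gc, linker_gc = linker_gc,
              linker_halfwidth = as.integer(linker_halfwidth),
              snp_rate_core = snp_rate_core,
              snp_rate_linker = snp_rate_linker,
              tss_at_5p = isTRUE(tss_at_5p),
              phased_flank = as.integer(phased_flank),
              holdout_chrom = holdout_chrom)
  class(cfg) <- "synthetic_config"
  cfg
}

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

#' Generate a synthetic chromatin dataset
#'
#' Produces the genome sequence, per-CpG methylation table, accessibility
#' cut positions (5' read ends, to be recentered with [shift_cuts()]), dyad
#' read positions, TSSs and SNPs, plus a `truth` record of everything the
#' generator planted.
#'
#' @param config a `synthetic_config`.
#' @return List of class `synthetic_dataset`: genome (`genome_sequence`),
#'   meth, cuts, dyad_reads, tss, snps (data.frames) and truth (list with
#'   hmds, linker_centers, dyads, motif_sites, tss, snps).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    lens <- setNames(rep(cfg$chrom_length, cfg$n_chrom), cfg$chroms)
    per_chrom <- cfg$n_hmds / cfg$n_chrom
    if (per_chrom != round(per_chrom))
      stop("n_hmds must be divisible by n_chrom")

    ## --- HMD layout: one HMD per equal-width slot, random offset ---------
    margin <- 1500L
    slot_w <- cfg$chrom_length %/% per_chrom
    if (slot_w - max(cfg$hmd_length_range) - 2L * margin <= 0)
      stop("chromosomes too short for the requested HMD count/length")
    hmds <- list()
    for (ch in cfg$chroms) {
      L <- as.integer(round(runif(per_chrom, cfg$hmd_length_range[1],
                                  cfg$hmd_length_range[2])))
      off <- vapply(L, function(l)
        margin + sample.int(slot_w - l - 2L * margin, 1L), integer(1))
      start <- (seq_len(per_chrom) - 1L) * slot_w + off
      hmds[[ch]] <- data.frame(chrom = ch, start = start, end = start + L,
                               strand = sample(c("+", "-"), per_chrom,
                                               replace = TRUE))
    }
    hmds <- do.call(rbind, hmds)
    rownames(hmds) <- NULL
    hmds$hmd_id <- seq_len(nrow(hmds))

    ## --- per-HMD internal layout in oriented coordinates -----------------
    # u = 0 at the 5' boundary; map to genome by strand
    map_u <- function(h, u) if (h$strand == "+") h$start + u else h$end - 1L - u
    linker_rows <- list(); dyad_rows <- list(); tss_rows <- list()
    for (i in seq_len(nrow(hmds))) {
      h <- hmds[i, ]
      L <- h$end - h$start
      # boundary linker sits at the HMD edge but fully inside it, so called
      # summits (which jitter by a few bp) stay within the domain
      lu <- cfg$linker_halfwidth
      nxt <- lu + cfg$boundary_gap_5p
      while (nxt <= L - 50L) {
        lu <- c(lu, nxt)
        nxt <- nxt + cfg$spacing_hmd
      }
      # dyads phased off the downstream linker: exact spacing_hmd lattice
      du <- if (length(lu) > 1) lu[-1] - cfg$spacing_hmd %/% 2L else integer(0)
      if (L - 1L - lu[length(lu)] >= 160L)
        du <- c(du, lu[length(lu)] + cfg$spacing_hmd %/% 2L)
      # methylated 5' flank: boundary-phased nucleosomes
      mu <- -(cfg$spacing_meth %/% 2L) -
        cfg$spacing_meth * (0:((cfg$phased_flank - cfg$spacing_meth %/% 2L) %/%
                                 cfg$spacing_meth))
      # methylated 3' flank, phased off the HMD end
      m3 <- (L - 1L) + cfg$spacing_meth %/% 2L +
        cfg$spacing_meth * (0:((cfg$phased_flank - cfg$spacing_meth %/% 2L) %/%
                                 cfg$spacing_meth))
      gl <- vapply(lu, function(u) map_u(h, u), numeric(1))
      gd <- vapply(c(du, mu, m3), function(u) map_u(h, u), numeric(1))
      gd <- gd[gd >= 0 & gd < cfg$chrom_length]
      linker_rows[[i]] <- data.frame(chrom = h$chrom, pos = as.integer(gl),
                                     hmd_id = h$hmd_id)
      dyad_rows[[i]] <- data.frame(chrom = h$chrom, pos = as.integer(gd),
                                   in_hmd = c(rep(TRUE, length(du)),
                                              rep(FALSE, length(mu) + length(m3)))[
                                                gd >= 0 & gd < cfg$chrom_length],
                                   hmd_id = h$hmd_id)
      if (cfg$tss_at_5p)
        tss_rows[[i]] <- data.frame(chrom = h$chrom,
                                    start = as.integer(map_u(h, lu[1])),
                                    strand = h$strand, hmd_id = h$hmd_id)
    }
    linkers <- do.call(rbind, linker_rows)
    dyads <- do.call(rbind, dyad_rows)
    tss <- if (length(tss_rows)) do.call(rbind, tss_rows) else
      data.frame(chrom = character(), start = integer(), strand = character())
    tss$end <- tss$start + 1L

    ## --- background nucleosome arrays between phased flanks --------------
    bg_dyads <- list()
    for (ch in cfg$chroms) {
      h <- hmds[hmds$chrom == ch, ]
      covered <- IRanges::reduce(IRanges::IRanges(
        pmax(h$start - cfg$phased_flank, 0L) + 1L,
        pmin(h$end + cfg$phased_flank, cfg$chrom_length)))
      gaps <- IRanges::gaps(covered, start = 1L, end = cfg$chrom_length)
      for (g in seq_along(gaps)) {
        a <- IRanges::start(gaps)[g] - 1L; b <- IRanges::end(gaps)[g]
        if (b - a < cfg$spacing_meth) next
        phase <- sample.int(cfg$spacing_meth, 1L) - 1L
        p <- seq(a + phase, b - 1L, by = cfg$spacing_meth)
        if (length(p))
          bg_dyads[[length(bg_dyads) + 1L]] <-
            data.frame(chrom = ch, pos = as.integer(p), in_hmd = FALSE,
                       hmd_id = NA_integer_)
      }
    }
    dyads <- rbind(dyads, do.call(rbind, bg_dyads))

    ## --- genome sequence --------------------------------------------------
    bases <- c("A", "C", "G", "T")
    chars <- list()
    for (ch in cfg$chroms)
      chars[[ch]] <- sample(bases, cfg$chrom_length, replace = TRUE,
                            prob = base_probs(cfg$background_gc))
    # GC-rich linker regions inside HMDs
    for (j in seq_len(nrow(linkers))) {
      ch <- linkers$chrom[j]
      a <- max(linkers$pos[j] - cfg$linker_halfwidth, 0L)
      b <- min(linkers$pos[j] + cfg$linker_halfwidth, cfg$chrom_length - 1L)
      h <- hmds[hmds$hmd_id == linkers$hmd_id[j], ]
      a <- max(a, h$start); b <- min(b, h$end - 1L)
      if (a <= b)
        chars[[ch]][(a:b) + 1L] <- sample(bases, b - a + 1L, replace = TRUE,
                                          prob = base_probs(cfg$linker_gc))
    }

    ## --- CpG grid + methylation ratios ------------------------------------
    meth_rows <- list()
    for (ch in cfg$chroms) {
      h <- hmds[hmds$chrom == ch, ]
      bgp <- seq(0L, cfg$chrom_length - 2L, by = cfg$cpg_spacing_bg)
      inh <- rep(FALSE, length(bgp))
      for (i in seq_len(nrow(h)))
        inh <- inh | (bgp >= h$start[i] & bgp < h$end[i])
      bgp <- bgp[!inh]
      hp <- unlist(lapply(seq_len(nrow(h)), function(i)
        seq(h$start[i], h$end[i] - 2L, by = cfg$cpg_spacing_hmd)))
      pos <- c(bgp, hp)
      ratio <- c(rbeta(length(bgp), cfg$meth_beta_bg[1], cfg$meth_beta_bg[2]),
                 rbeta(length(hp), cfg$meth_beta_hmd[1], cfg$meth_beta_hmd[2]))
      o <- order(pos)
      meth_rows[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos[o]),
                                    ratio = ratio[o])
      # write the CpG dinucleotides into the sequence
      chars[[ch]][pos + 1L] <- "C"
      chars[[ch]][pos + 2L] <- "G"
    }
    meth <- do.call(rbind, meth_rows)

    ## --- plant motifs at linker centers (inside the HMD only) -------------
    motif_rows <- list()
    half_m <- 3L
    for (j in seq_len(nrow(linkers))) {
      if (runif(1) >= cfg$motif_plant_prob) next
      km <- sample(cfg$linker_motifs, 1L)
      s <- linkers$pos[j] - half_m
      h <- hmds[hmds$hmd_id == linkers$hmd_id[j], ]
      if (s < h$start || s + 6L > h$end) next  # boundary linker: no room
      chars[[linkers$chrom[j]]][(s + 1L):(s + 6L)] <- strsplit(km, "")[[1]]
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(chrom = linkers$chrom[j], start = as.integer(s),
                   kmer = km, hmd_id = linkers$hmd_id[j],
                   linker_center = linkers$pos[j])
    }
    motif_sites <- if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(chrom = character(), start = integer(), kmer = character(),
                 hmd_id = integer(), linker_center = integer())
    # drop CpG records clobbered by a motif
    if (nrow(motif_sites)) {
      drop <- rep(FALSE, nrow(meth))
      for (j in seq_len(nrow(motif_sites))) {
        drop <- drop | (meth$chrom == motif_sites$chrom[j] &
                          meth$pos >= motif_sites$start[j] - 1L &
                          meth$pos <= motif_sites$start[j] + 5L)
      }
      meth <- meth[!drop, , drop = FALSE]
    }
    genome <- genome_sequence(vapply(chars, paste, character(1), collapse = ""))

    ## --- accessibility cuts (5' read ends; recenter with shift_cuts) ------
    nlk <- nrow(linkers)
    ncut <- rpois(nlk, cfg$cuts_per_linker)
    cut_center <- rep(linkers$pos, ncut) +
      round(rnorm(sum(ncut), 0, cfg$cut_jitter_sd))
    cut_chrom <- rep(linkers$chrom, ncut)
    cut_strand <- sample(c("+", "-"), sum(ncut), replace = TRUE)
    cut_pos <- cut_center + ifelse(cut_strand == "+", 50L, -50L)
    nbg <- rpois(1L, cfg$background_cut_rate * cfg$chrom_length * cfg$n_chrom)
    bg_chrom <- sample(cfg$chroms, nbg, replace = TRUE)
    bg_pos <- floor(runif(nbg, 0, cfg$chrom_length))
    cuts <- data.frame(
      chrom = c(cut_chrom, bg_chrom),
      pos = as.integer(pmax(0L, pmin(c(cut_pos, bg_pos),
                                     cfg$chrom_length - 1L))),
      strand = c(cut_strand, sample(c("+", "-"), nbg, replace = TRUE)))

    ## --- dyad reads --------------------------------------------------------
    nrd <- rpois(nrow(dyads), cfg$reads_per_dyad)
    rd_pos <- rep(dyads$pos, nrd) + round(rnorm(sum(nrd), 0, cfg$dyad_jitter_sd))
    dyad_reads <- data.frame(
      chrom = rep(dyads$chrom, nrd),
      pos = as.integer(pmax(0L, pmin(rd_pos, cfg$chrom_length - 1L))))

    ## --- SNPs: depleted in HMD linkers -------------------------------------
    snp_rows <- list()
    for (ch in cfg$chroms) {
      n <- rpois(1L, cfg$snp_rate_core * cfg$chrom_length)
      p <- sort(unique(floor(runif(n, 0, cfg$chrom_length))))
      lk <- linkers[linkers$chrom == ch, ]
      if (nrow(lk)) {
        inlk <- rep(FALSE, length(p))
        for (j in seq_len(nrow(lk)))
          inlk <- inlk | abs(p - lk$pos[j]) <= cfg$linker_halfwidth
        # thin core-rate SNPs in linkers down to the linker rate
        keep <- !inlk | (runif(length(p)) <
                           cfg$snp_rate_linker / cfg$snp_rate_core)
        p <- p[keep]
      }
      snp_rows[[ch]] <- data.frame(chrom = ch, pos = as.integer(p))
    }
    snps <- do.call(rbind, snp_rows)

    truth <- list(hmds = hmds, linker_centers = linkers, dyads = dyads,
                  motif_sites = motif_sites, tss = tss, snps = snps)
    structure(list(genome = genome,
                   meth = meth[order(meth$chrom, meth$pos), ],
                   cuts = cuts[order(cuts$chrom, cuts$pos), ],
                   dyad_reads = dyad_reads[order(dyad_reads$chrom,
                                                 dyad_reads$pos), ],
                   tss = tss, snps = snps, truth = truth, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", x$config$n_chrom, " x ",
      x$config$chrom_length, " bp, ", nrow(x$truth$hmds), " HMDs, ",
      nrow(x$cuts), " cuts, ", nrow(x$dyad_reads), " dyad reads (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Degrade a synthetic dataset
#'
#' Thins accessibility cuts and inflates positional jitter of cuts and dyad
#' reads; `level = 0` is the identity, `level = 1` approaches uninformative
#' tracks. Used for robustness curves.
#'
#' @param ds a `synthetic_dataset`.
#' @param level degradation level in `[0, 1]`.
#' @return A degraded `synthetic_dataset` (truth unchanged).
#' @export
degrade <- function(ds, level) {
  if (level < 0 || level > 1) stop("level must be in [0,1]")
  if (level == 0) return(ds)
  with_seed(ds$config$seed + 7919L, {
    keep <- runif(nrow(ds$cuts)) < (1 - 0.9 * level)
    cuts <- ds$cuts[keep, , drop = FALSE]
    jit <- function(df) {
      df$pos <- as.integer(pmax(0L, pmin(
        df$pos + round(rnorm(nrow(df), 0, 60 * level)),
        ds$config$chrom_length - 1L)))
      df
    }
    ds$cuts <- jit(cuts)
    ds$dyad_reads <- jit(ds$dyad_reads)
    ds
  })
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits genome.fa, meth.tsv, dnase_cuts.bed (BED6, pos = 5' read end),
#' mnase_dyads.bed, tss.bed (BED6), snps.bed and truth.json under `dir`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$genome, file.path(dir, "genome.fa"))
  write_methylation(ds$meth, file.path(dir, "meth.tsv"))
  cuts <- data.frame(chrom = ds$cuts$chrom, start = ds$cuts$pos,
                     end = ds$cuts$pos + 1L, name = ".", score = 0,
                     strand = ds$cuts$strand)
  write_intervals(cuts, file.path(dir, "dnase_cuts.bed"))
  dy <- data.frame(chrom = ds$dyad_reads$chrom, start = ds$dyad_reads$pos,
                   end = ds$dyad_reads$pos + 1L)
  write_intervals(dy, file.path(dir, "mnase_dyads.bed"))
  tss <- data.frame(chrom = ds$tss$chrom, start = ds$tss$start,
                    end = ds$tss$end, name = ".", score = 0,
                    strand = ds$tss$strand)
  write_intervals(tss, file.path(dir, "tss.bed"))
  write_intervals(data.frame(chrom = ds$snps$chrom, start = ds$snps$pos,
                             end = ds$snps$pos + 1L),
                  file.path(dir, "snps.bed"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
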