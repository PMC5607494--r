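## End-to-end orchestration: simulate -> call HMDs -> summits -> anchors ->
## metaprofiles -> spacing -> train/evaluate SVMs -> periodicity -> report.
## Every stage is an exported function; run_pipeline() wires them in
## dependency order and collects a machine-readable report. All randomness
## flows from the seed in the simulation config, so a rerun with the same
## config reproduces the report exactly.

#' Pipeline configuration
#'
#' @param sim a `synthetic_config` (inputs and master seed).
#' @param shift cut 5'-shift in bp.
#' @param smooth_bw coverage boxcar width in bp.
#' @param min_separation summit exclusion radius in bp.
#' @param fold_enrichment summit fold-over-median criterion.
#' @param flank metaprofile half-window in bp.
#' @param k,C SVM k-mer length and soft-margin penalty.
#' @param top_n_periodicity k-mers used for the distance histogram.
#' @param top_n_compare k-mers for the weight comparison test.
#' @param alpha significance level for per-HMD correlations.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = synthetic_config(), shift = 50L,
                            smooth_bw = 73L, min_separation = 100L,
                            fold_enrichment = 5, flank = 1000L, k = 6L,
                            C = 1.0, top_n_periodicity = 10L,
                            top_n_compare = 20L, alpha = 0.05) {
  cfg <- list(sim = sim, shift = shift, smooth_bw = smooth_bw,
              min_separation = min_separation,
              fold_enrichment = fold_enrichment, flank = flank, k = k, C = C,
              top_n_periodicity = top_n_periodicity,
              top_n_compare = top_n_compare, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' @param config a `pipeline_config`.
#' @param dataset optionally a pre-generated `synthetic_dataset` (must match
#'   `config$sim`); generated when `NULL`.
#' @param out_dir optional directory; when given, intermediates (hmds.bed,
#'   summits.bed, profiles, models, report.json) are written there.
#' @param quiet suppress progress messages.
#' @return List of class `pipeline_report` (see fields in the source);
#'   intermediates attached as `attr(report, "state")`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[hmdnuc] ", ...)
  cfg <- config
  ds <- if (is.null(dataset)) {
    say("simulate: generating synthetic dataset (seed ", cfg$sim$seed, ")")
    generate_synthetic(cfg$sim)
  } else dataset
  lens <- chrom_lengths(ds$genome)

  say("call-hmds: ", nrow(ds$meth), " CpGs")
  hmds <- call_hmds(ds$meth)

  say("summits: coverage + local maxima")
  shifted <- shift_cuts(ds$cuts, cfg$shift, lens)
  cov <- cut_coverage(shifted, lens, smooth_bw = cfg$smooth_bw)
  summits <- call_summits(cov, min_separation = cfg$min_separation,
                          fold_enrichment = cfg$fold_enrichment)
  ostats <- overlap_stats(summits, hmds, ds$genome)

  say("profiles: anchors + metaprofiles")
  anchors <- select_anchors(hmds, summits, ds$tss)
  a5 <- anchors[anchors$side == "5p", , drop = FALSE]
  dyad_track <- count_track(ds$dyad_reads, lens)
  prof_dyad <- metaprofile(dyad_track, a5, flank = cfg$flank)
  prof_dnase <- metaprofile(cov, a5, flank = cfg$flank)

  say("spacing: autocorrelation")
  sp_hmd <- estimate_spacing(prof_dyad, "hmd")
  sp_meth <- estimate_spacing(prof_dyad, "methylated")
  gap5 <- boundary_linker_gap(prof_dnase)

  say("train: SVM_DNaseI (linker vs core)")
  sets_dnase <- build_linker_core_sets(hmds, summits, ds$genome,
                                       holdout_chrom = cfg$sim$holdout_chrom)
  m_dnase <- train_kmer_svm(sets_dnase, k = cfg$k, C = cfg$C)
  eval_dnase <- evaluate_model(m_dnase, sets_dnase)

  say("periodicity: top-", cfg$top_n_periodicity, " k-mer distances")
  top <- top_kmers(m_dnase, cfg$top_n_periodicity)
  occ <- kmer_occurrences(ds$genome, hmds, top)
  dhist <- pairwise_distance_histogram(occ)

  say("train: SVM_hypo (HMD vs methylated)")
  sets_hypo <- build_hmd_vs_methylated_sets(
    hmds, ds$genome, seed = cfg$sim$seed + 1L,
    holdout_chrom = cfg$sim$holdout_chrom)
  m_hypo <- train_kmer_svm(sets_hypo, k = cfg$k, C = cfg$C)
  eval_hypo <- evaluate_model(m_hypo, sets_hypo)
  wcmp <- compare_weights(m_dnase, m_hypo, cfg$top_n_compare)

  say("score: per-HMD correlation on holdout ", cfg$sim$holdout_chrom)
  hold <- hmds[hmds$chrom == cfg$sim$holdout_chrom &
                 (hmds$end - hmds$start) >= 100L, , drop = FALSE]
  scored <- lapply(seq_len(nrow(hold)), function(i) {
    correlate_scores(score_hmd(hold[i, ], ds$genome, m_dnase), cov)
  })
  chist <- correlation_histogram(scored, alpha = cfg$alpha)

  report <- structure(list(
    n_hmds = nrow(hmds),
    n_summits = nrow(summits),
    overlap_stats = ostats,
    n_anchors_5p = nrow(a5),
    spacing_hmd_bp = sp_hmd$spacing,
    spacing_methylated_bp = sp_meth$spacing,
    spacing_confident = c(hmd = sp_hmd$confident, meth = sp_meth$confident),
    boundary_linker_gap_bp = gap5,
    auc_dnase = eval_dnase$auc, auprc_dnase = eval_dnase$auprc,
    auc_hypo = eval_hypo$auc, auprc_hypo = eval_hypo$auprc,
    top_kmers = setNames(as.numeric(m_dnase$weights[top]), top),
    periodicity_mode_bp = dhist$mode_bin_center,
    weight_comparison_p = wcmp$rank_test_p,
    n_hmds_scored = chist$n_total,
    n_significant = chist$n_significant,
    n_significant_positive = chist$n_significant_positive,
    provenance = list(seed = cfg$sim$seed,
                      holdout_chrom = cfg$sim$holdout_chrom,
                      package_version = as.character(
                        utils::packageVersion("hmdnuc")))),
    class = "pipeline_report")
  attr(report, "state") <- list(
    dataset = ds, hmds = hmds, coverage = cov, summits = summits,
    anchors = anchors, prof_dyad = prof_dyad, prof_dnase = prof_dnase,
    spacing = list(hmd = sp_hmd, methylated = sp_meth),
    sets_dnase = sets_dnase, model_dnase = m_dnase, eval_dnase = eval_dnase,
    sets_hypo = sets_hypo, model_hypo = m_hypo, eval_hypo = eval_hypo,
    weight_comparison = wcmp, distance_histogram = dhist, scored = scored)

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n",
      "  HMDs: ", x$n_hmds, "  summits: ", x$n_summits,
      "  (", round(100 * x$overlap_stats$frac_genome_hmd, 1), "% of genome)\n",
      "  spacing: HMD ", x$spacing_hmd_bp, " bp / methylated ",
      x$spacing_methylated_bp, " bp; 5' boundary gap ",
      x$boundary_linker_gap_bp, " bp\n",
      "  AUC: DNaseI ", round(x$auc_dnase, 3), ", hypo ",
      round(x$auc_hypo, 3), "\n",
      "  periodicity mode: ", x$periodicity_mode_bp, " bp; significant HMDs ",
      x$n_significant, "/", x$n_hmds_scored, "\n", sep = "")
  invisible(x)
}

#' Write pipeline intermediates and report.json
#'
#' @param report a `pipeline_report` (with attached state).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- attr(report, "state")
  hm <- st$hmds
  write_intervals(data.frame(chrom = hm$chrom, start = hm$start,
                             end = hm$end, name = paste0("hmd", hm$hmd_id),
                             score = hm$n_cpgs),
                  file.path(dir, "hmds.bed"))
  write_intervals(data.frame(chrom = st$summits$chrom,
                             start = st$summits$pos,
                             end = st$summits$pos + 1L, name = ".",
                             score = st$summits$height),
                  file.path(dir, "summits.bed"))
  for (p in c("prof_dyad", "prof_dnase"))
    data.table::fwrite(as.data.frame(st[[p]]),
                       file.path(dir, paste0(sub("prof_", "profile_", p),
                                             ".tsv")), sep = "\t")
  write_kmer_model(st$model_dnase, file.path(dir, "svm_dnase"))
  write_kmer_model(st$model_hypo, file.path(dir, "svm_hypo"))
  dh <- st$distance_histogram
  data.table::fwrite(data.frame(bin_start = dh$bin_start,
                                bin_end = dh$bin_end, count = dh$count),
                     file.path(dir, "distance_histogram.tsv"), sep = "\t")
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
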