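## k-mer spectrum SVMs: training-set construction from accessible linkers
## vs nucleosome cores (SVM_DNaseI) and HMDs vs methylated background
## (SVM_hypo), feature extraction, a linear soft-margin SVM trained by dual
## coordinate descent (compiled), sliding-window HMD scoring, and
## evaluation (per-HMD correlation, ROC/PR, weight comparison).

all_kmers <- function(k) {
  mkAllStrings <- Biostrings::mkAllStrings
  mkAllStrings(c("A", "C", "G", "T"), k)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' k-mer spectrum feature matrix
#'
#' Counts every overlapping k-mer of each sequence on the given strand.
#' With `revcomp_collapse`, counts of a k-mer and its reverse complement are
#' pooled into one canonical feature. With `normalize`, each row is scaled
#' to unit Euclidean norm (required when sequence lengths differ between
#' examples).
#'
#' @param seqs character vector of ACGT sequences (no N), each at least
#'   `k` long.
#' @param k k-mer length.
#' @param normalize scale rows to unit L2 norm.
#' @param revcomp_collapse pool reverse-complement pairs.
#' @return Sparse `dgCMatrix` (`Matrix`), one row per sequence, k-mers as
#'   column names.
#' @export
kmer_features <- function(seqs, k, normalize = TRUE, revcomp_collapse = FALSE) {
  if (any(grepl("[^ACGT]", seqs))) stop("sequences must contain only ACGT")
  if (any(nchar(seqs) < k)) stop("sequence shorter than k")
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  if (revcomp_collapse) {
    km <- colnames(m)
    canon <- pmin(km, revcomp(km))
    grp <- split(seq_along(km), canon)
    m2 <- vapply(grp, function(ix) {
      if (length(ix) == 2L) m[, ix[1]] + m[, ix[2]] else m[, ix[1]]
    }, numeric(nrow(m)))
    if (nrow(m) == 1L) m2 <- matrix(m2, nrow = 1, dimnames = list(NULL, names(grp)))
    m <- m2
  }
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    m <- m / pmax(nrm, .Machine$double.eps)
  }
  Matrix::Matrix(m, sparse = TRUE)
}

new_labeled_seq_set <- function(positives, negatives, holdout_chrom,
                                n_dropped) {
  structure(list(positives = positives, negatives = negatives,
                 holdout_chrom = holdout_chrom, n_dropped = n_dropped),
            class = "labeled_seq_set")
}

#' @export
print.labeled_seq_set <- function(x, ...) {
  cat("<labeled_seq_set> ", nrow(x$positives), " positives, ",
      nrow(x$negatives), " negatives (holdout: ", x$holdout_chrom, "; ",
      x$n_dropped, " dropped for N)\n", sep = "")
  invisible(x)
}

# extract fixed-length windows, dropping those leaving [lo, hi) or containing N
extract_windows <- function(genome, chrom, centers, seq_len, lo, hi) {
  half <- seq_len %/% 2L
  start <- centers - half
  end <- start + seq_len
  keep <- start >= lo & end <= hi
  start <- start[keep]; end <- end[keep]
  if (!length(start))
    return(list(df = data.frame(seq = character(), chrom = character(),
                                start = integer(), end = integer()),
                n_dropped = 0L))
  seqs <- get_sequence(genome, chrom, start, end)
  hasN <- grepl("N", seqs, fixed = TRUE)
  list(df = data.frame(seq = seqs[!hasN], chrom = chrom,
                       start = start[!hasN], end = end[!hasN]),
       n_dropped = sum(hasN))
}

#' Build linker (positive) vs nucleosome-core (negative) sequence sets
#'
#' Positives are `seq_len`-bp sequences centered on each in-HMD summit
#' (accessible linker). Negatives are `seq_len`-bp sequences centered on the
#' midpoint of each pair of adjacent in-HMD summits whose distance exceeds
#' `min_summit_gap` (the presumed nucleosome core between two linkers).
#' Windows crossing the HMD edge and windows containing N are dropped.
#'
#' @param hmds an `hmd_set`.
#' @param summits data.frame with chrom, pos.
#' @param genome a `genome_sequence`.
#' @param seq_len window length (must be even; centered as `[c - L/2, c + L/2)`).
#' @param min_summit_gap adjacent summits closer than this yield no negative.
#' @param holdout_chrom chromosome reserved for testing.
#' @return A `labeled_seq_set`.
#' @export
build_linker_core_sets <- function(hmds, summits, genome, seq_len = 100L,
                                   min_summit_gap = 150L, holdout_chrom) {
  if (seq_len %% 2L != 0L) stop("seq_len must be even")
  pos <- list(); neg <- list(); dropped <- 0L
  for (i in seq_len(nrow(hmds))) {
    ch <- hmds$chrom[i]
    sp <- sort(summits$pos[summits$chrom == ch &
                           summits$pos >= hmds$start[i] &
                           summits$pos < hmds$end[i]])
    if (!length(sp)) next
    wp <- extract_windows(genome, ch, sp, seq_len, hmds$start[i], hmds$end[i])
    pos[[length(pos) + 1L]] <- wp$df; dropped <- dropped + wp$n_dropped
    if (length(sp) > 1) {
      gaps <- diff(sp)
      mids <- (sp[-length(sp)] + sp[-1]) %/% 2L
      mids <- mids[gaps > min_summit_gap]
      if (length(mids)) {
        wn <- extract_windows(genome, ch, mids, seq_len,
                              hmds$start[i], hmds$end[i])
        neg[[length(neg) + 1L]] <- wn$df; dropped <- dropped + wn$n_dropped
      }
    }
  }
  new_labeled_seq_set(do.call(rbind, pos), do.call(rbind, neg),
                      holdout_chrom, dropped)
}

#' Build HMD (positive) vs methylated-background (negative) sequence sets
#'
#' Positives are all HMD sequences shorter than `max_len`. For each positive,
#' `neg_copies` intervals of identical length are placed uniformly at random
#' on the methylated part of the genome (never intersecting any HMD).
#' Sequences containing N are dropped and counted.
#'
#' @param hmds an `hmd_set`.
#' @param genome a `genome_sequence`.
#' @param max_len strict upper bound on HMD length (bp).
#' @param neg_copies negatives per positive.
#' @param seed RNG seed for the random placement (private stream).
#' @param holdout_chrom chromosome reserved for testing.
#' @param max_tries placement retries per negative before erroring.
#' @return A `labeled_seq_set`.
#' @export
build_hmd_vs_methylated_sets <- function(hmds, genome, max_len = 3000L,
                                         neg_copies = 10L, seed = 1L,
                                         holdout_chrom, max_tries = 1000L) {
  lens <- chrom_lengths(genome)
  keep <- (hmds$end - hmds$start) < max_len
  hp <- hmds[keep, , drop = FALSE]
  dropped <- 0L
  pseqs <- character(nrow(hp))
  for (i in seq_len(nrow(hp)))
    pseqs[i] <- get_sequence(genome, hp$chrom[i], hp$start[i], hp$end[i])
  hasN <- grepl("N", pseqs, fixed = TRUE)
  dropped <- dropped + sum(hasN)
  positives <- data.frame(seq = pseqs[!hasN], chrom = hp$chrom[!hasN],
                          start = hp$start[!hasN], end = hp$end[!hasN])
  negatives <- with_seed(seed, {
    out <- vector("list", nrow(positives))
    for (i in seq_len(nrow(positives))) {
      L <- positives$end[i] - positives$start[i]
      placed <- 0L; tries <- 0L
      rows <- list()
      while (placed < neg_copies) {
        tries <- tries + 1L
        if (tries > max_tries * neg_copies)
          stop("failed to place negative intervals on methylated space")
        ch <- sample(names(lens), 1L, prob = lens)
        if (lens[[ch]] <= L) next
        st <- sample.int(lens[[ch]] - L, 1L) - 1L
        cand <- data.frame(chrom = ch, start = st, end = st + L)
        if (overlap_bp(cand, hmds) > 0) next
        sq <- get_sequence(genome, ch, st, st + L)
        if (grepl("N", sq, fixed = TRUE)) { dropped <- dropped + 1L; next }
        placed <- placed + 1L
        rows[[placed]] <- data.frame(seq = sq, chrom = ch, start = st,
                                     end = st + L)
      }
      out[[i]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
  new_labeled_seq_set(positives, negatives, holdout_chrom, dropped)
}

#' Train a linear k-mer spectrum SVM
#'
#' Fits an L2-regularized L1-loss (soft-margin) linear SVM on k-mer spectrum
#' features by deterministic dual coordinate descent. Only sequences NOT on
#' the holdout chromosome are used.
#'
#' @param sets a `labeled_seq_set`.
#' @param k k-mer length (default 6).
#' @param C soft-margin penalty.
#' @param normalize unit-normalize feature vectors (required when sequence
#'   lengths differ).
#' @param revcomp_collapse pool reverse-complement k-mer pairs.
#' @param max_iter,tol optimizer controls.
#' @return Object of class `kmer_model`: k, weights (named per k-mer), bias,
#'   C, normalize, revcomp_collapse, training_meta.
#' @export
train_kmer_svm <- function(sets, k = 6L, C = 1.0, normalize = TRUE,
                           revcomp_collapse = FALSE, max_iter = 2000L,
                           tol = 1e-4) {
  tr_pos <- sets$positives[sets$positives$chrom != sets$holdout_chrom, ]
  tr_neg <- sets$negatives[sets$negatives$chrom != sets$holdout_chrom, ]
  if (!nrow(tr_pos) || !nrow(tr_neg)) stop("single-class training input")
  seqs <- c(tr_pos$seq, tr_neg$seq)
  y <- c(rep(1, nrow(tr_pos)), rep(-1, nrow(tr_neg)))
  # class-independent deterministic example order: the optimizer visits
  # examples cyclically, so this makes label-swapped training exactly
  # antisymmetric
  o <- order(c(tr_pos$chrom, tr_neg$chrom), c(tr_pos$start, tr_neg$start),
             seqs, y)
  seqs <- seqs[o]
  y <- y[o]
  X <- kmer_features(seqs, k, normalize = normalize,
                     revcomp_collapse = revcomp_collapse)
  fit <- svm_dcd(Matrix::t(X), y, C, as.integer(max_iter), tol, 1.0)
  structure(list(k = as.integer(k),
                 weights = setNames(fit$weights, colnames(X)),
                 bias = fit$bias, C = C, normalize = normalize,
                 revcomp_collapse = revcomp_collapse,
                 training_meta = list(n_pos = nrow(tr_pos),
                                      n_neg = nrow(tr_neg),
                                      holdout_chrom = sets$holdout_chrom,
                                      iterations = fit$iterations,
                                      converged = fit$converged)),
            class = "kmer_model")
}

#' @export
print.kmer_model <- function(x, ...) {
  tw <- sort(x$weights, decreasing = TRUE)
  cat("<kmer_model> k=", x$k, ", C=", x$C, ", ",
      length(x$weights), " features; trained on ",
      x$training_meta$n_pos, "+/", x$training_meta$n_neg, "- (holdout ",
      x$training_meta$holdout_chrom, ")\n  top weights: ",
      paste0(names(tw)[1:3], "=", signif(tw[1:3], 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' SVM decision values for sequences
#'
#' `w . features(seq) + b` under the model's feature conventions.
#'
#' @param model a `kmer_model`.
#' @param seqs character vector of ACGT sequences.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, seqs) {
  X <- kmer_features(seqs, model$k, normalize = model$normalize,
                     revcomp_collapse = model$revcomp_collapse)
  as.numeric(X %*% model$weights) + model$bias
}

#' Score an HMD by sliding-window SVM decision values
#'
#' Decision values are computed for every `window`-bp window starting at
#' each `step`-bp grid point inside the HMD; the score of each `step`-bp
#' step is the mean decision value of all windows overlapping that step
#' (five in the interior for 100/20, fewer at the edges). Windows containing
#' N give undefined decisions and are excluded.
#'
#' @param hmd single row of an `hmd_set`.
#' @param genome a `genome_sequence`.
#' @param model a `kmer_model`.
#' @param window window length in bp (multiple of `step`).
#' @param step step size in bp.
#' @return Object of class `scored_hmd`: hmd_id, chrom, step_start
#'   (absolute bp of each step), score, window_start, decision, r, p.
#' @export
score_hmd <- function(hmd, genome, model, window = 100L, step = 20L) {
  if (window %% step != 0) stop("window must be a multiple of step")
  len <- hmd$end - hmd$start
  if (len < window) stop("HMD shorter than window")
  wstart <- seq(0L, len - window, by = step)
  seqs <- get_sequence(genome, hmd$chrom, hmd$start + wstart,
                       hmd$start + wstart + window)
  dec <- rep(NA_real_, length(wstart))
  ok <- !grepl("N", seqs, fixed = TRUE)
  if (any(ok)) dec[ok] <- decision_values(model, seqs[ok])
  sstart <- seq(0L, len - step, by = step)
  score <- vapply(sstart, function(a) {
    ov <- wstart < a + step & wstart + window > a
    d <- dec[ov]
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }, numeric(1))
  structure(list(hmd_id = hmd$hmd_id, chrom = hmd$chrom,
                 step_start = hmd$start + sstart, step = step,
                 score = score, window_start = hmd$start + wstart,
                 decision = dec, r = NA_real_, p = NA_real_),
            class = "scored_hmd")
}

#' Correlate per-step SVM scores with a signal track
#'
#' The per-step signal is the mean track value over each step interval;
#' Pearson r and its two-sided P value (t distribution, df = n - 2) are
#' filled into the scored HMD.
#'
#' @param scored a `scored_hmd`.
#' @param track a `signal_track`.
#' @return The `scored_hmd` with `signal`, `r`, `p` filled; `r` is `NA`
#'   (flagged via `degenerate = TRUE`) when either side has zero variance or
#'   fewer than 3 complete steps exist.
#' @export
correlate_scores <- function(scored, track) {
  v <- track$values[[scored$chrom]]
  sig <- vapply(scored$step_start, function(a) {
    x <- v[(a + 1L):(a + scored$step)]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  scored$signal <- sig
  ok <- !is.na(sig) & !is.na(scored$score)
  scored$degenerate <- FALSE
  if (sum(ok) < 3 || stats::sd(scored$score[ok]) == 0 ||
      stats::sd(sig[ok]) == 0) {
    scored$degenerate <- TRUE
    return(scored)
  }
  ct <- cor.test(scored$score[ok], sig[ok], method = "pearson")
  scored$r <- unname(ct$estimate)
  scored$p <- ct$p.value
  scored
}

#' Summarize score-signal correlations over many HMDs
#'
#' @param scored_list list of correlated `scored_hmd` objects.
#' @param alpha significance level on the raw two-sided P value.
#' @return List: n_significant, n_significant_positive, n_total, and a
#'   histogram of r over bins of width 0.1 on `[-1, 1]`.
#' @export
correlation_histogram <- function(scored_list, alpha = 0.05) {
  r <- vapply(scored_list, `[[`, numeric(1), "r")
  p <- vapply(scored_list, `[[`, numeric(1), "p")
  ok <- !is.na(r)
  breaks <- seq(-1, 1, by = 0.1)
  h <- table(cut(r[ok], breaks, include.lowest = TRUE))
  list(n_significant = sum(p[ok] < alpha),
       n_significant_positive = sum(p[ok] < alpha & r[ok] > 0),
       n_total = length(r),
       hist = data.frame(bin_low = head(breaks, -1),
                         bin_high = breaks[-1],
                         count = as.integer(h)))
}

#' ROC and precision-recall evaluation on the holdout chromosome
#'
#' Decision values are computed for the holdout-chromosome sequences of
#' `sets`; the ROC curve (trapezoid AUC) and precision-recall curve are
#' built by a threshold sweep over the distinct decision values.
#'
#' @param model a `kmer_model`.
#' @param sets the `labeled_seq_set` the model was built from (its holdout
#'   chromosome supplies the test data).
#' @return List: roc (fpr, tpr), auc, pr (recall, precision), auprc,
#'   n_pos, n_neg.
#' @export
evaluate_model <- function(model, sets) {
  te_pos <- sets$positives[sets$positives$chrom == sets$holdout_chrom, ]
  te_neg <- sets$negatives[sets$negatives$chrom == sets$holdout_chrom, ]
  if (!nrow(te_pos) || !nrow(te_neg)) stop("single-class test set")
  scores <- decision_values(model, c(te_pos$seq, te_neg$seq))
  labels <- c(rep(1L, nrow(te_pos)), rep(0L, nrow(te_neg)))
  roc_pr(scores, labels)
}

#' ROC/PR curves from scores and binary labels
#'
#' @param scores numeric decision values.
#' @param labels 0/1 labels.
#' @return List with roc, auc, pr, auprc, n_pos, n_neg.
#' @export
roc_pr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("single-class input")
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  rec <- tp / P
  prec <- tp / (tp + fp)
  # step-wise AUPRC (average precision style, over recall increments)
  drec <- diff(c(0, rec))
  auprc <- sum(prec * drec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       auc = auc,
       pr = data.frame(recall = rec, precision = prec),
       auprc = auprc, n_pos = P, n_neg = N)
}

#' Compare per-k-mer weights between two models
#'
#' Scatter pairs of weights for all k-mers plus a two-sided unpaired
#' Wilcoxon rank-sum test comparing the `model_b` weights of the `top_n`
#' highest-weight k-mers of `model_a` against the weights of all k-mers.
#'
#' @param model_a reference model supplying the top-n ranking (e.g.
#'   the linker model).
#' @param model_b model whose weights are tested (e.g. the HMD model).
#' @param top_n number of top `model_a` k-mers.
#' @return List: pairs (kmer, w_a, w_b), top_kmers, rank_test_p.
#' @export
compare_weights <- function(model_a, model_b, top_n = 20L) {
  if (model_a$k != model_b$k) stop("k mismatch")
  if (model_a$revcomp_collapse != model_b$revcomp_collapse)
    stop("collapse-mode mismatch")
  km <- names(model_a$weights)
  stopifnot(identical(sort(km), sort(names(model_b$weights))))
  wb <- model_b$weights[km]
  top <- top_kmers(model_a, top_n)
  wt <- suppressWarnings(
    wilcox.test(wb[top], wb, alternative = "two.sided", exact = FALSE))
  list(pairs = data.frame(kmer = km, w_a = unname(model_a$weights[km]),
                          w_b = unname(wb)),
       top_kmers = top, rank_test_p = wt$p.value)
}

#' Top-weight k-mers of a model
#'
#' @param model a `kmer_model`.
#' @param n number of k-mers (largest signed weight; ties lexicographic).
#' @return Character vector of k-mers.
#' @export
top_kmers <- function(model, n = 10L) {
  if (n > length(model$weights)) stop("n exceeds number of k-mers")
  o <- order(-model$weights, names(model$weights))
  names(model$weights)[o][seq_len(n)]
}

#' Serialize / read a k-mer model
#'
#' Weights go to a TSV (kmer, weight); scalar metadata to a JSON sidecar
#' (`<prefix>.json`).
#'
#' @param model a `kmer_model`.
#' @param prefix output path prefix (writes `<prefix>.tsv` + `<prefix>.json`).
#' @return The prefix, invisibly.
#' @export
write_kmer_model <- function(model, prefix) {
  data.table::fwrite(data.table::data.table(kmer = names(model$weights),
                                            weight = model$weights),
                     paste0(prefix, ".tsv"), sep = "\t")
  meta <- model[c("k", "bias", "C", "normalize", "revcomp_collapse",
                  "training_meta")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_kmer_model
#' @export
read_kmer_model <- function(prefix) {
  w <- data.table::fread(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(k = as.integer(meta$k),
                 weights = setNames(w$weight, w$kmer), bias = meta$bias,
                 C = meta$C, normalize = meta$normalize,
                 revcomp_collapse = meta$revcomp_collapse,
                 training_meta = meta$training_meta),
            class = "kmer_model")
}
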