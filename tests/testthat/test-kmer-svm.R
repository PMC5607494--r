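test_that("kmer_features counts overlapping k-mers", {
  X <- kmer_features("ACGTAC", 2, normalize = FALSE)
  v <- setNames(as.numeric(X[1, ]), colnames(X))
  expect_equal(unname(v[c("AC", "CG", "GT", "TA")]), c(2, 1, 1, 1))
  expect_equal(sum(v), 5)
  expect_equal(sqrt(sum(kmer_features("ACGTAC", 2)[1, ]^2)), 1)
  expect_error(kmer_features("ACGNAC", 2), "ACGT")
  expect_error(kmer_features("AC", 3), "shorter")
})

test_that("kmer_features matches the naive counter on random sequences", {
  withr::local_seed(41)
  for (k in c(2L, 3L)) {
    seqs <- vapply(1:10, function(i) random_dna(sample(20:80, 1)), "")
    X <- kmer_features(seqs, k, normalize = FALSE)
    for (i in seq_along(seqs)) {
      want <- naive_kmer_counts(seqs[i], k)
      expect_equal(setNames(as.numeric(X[i, ]), colnames(X)), want)
    }
  }
})

test_that("reverse-complement collapse pools paired columns", {
  X <- kmer_features("ACGTACGT", 2, normalize = FALSE, revcomp_collapse = TRUE)
  # canonical AC pools AC + GT
  full <- kmer_features("ACGTACGT", 2, normalize = FALSE)
  expect_equal(as.numeric(X[1, "AC"]),
               as.numeric(full[1, "AC"] + full[1, "GT"]))
  # palindromic 2-mers (AT, TA, CG, GC) are single columns, counted once
  expect_equal(as.numeric(X[1, "CG"]), as.numeric(full[1, "CG"]))
  expect_equal(ncol(X), 10)  # 4^2/2 + 2 palindrome-free pairs = 6 + 4
})

test_that("build_linker_core_sets implements the summit/midpoint rules", {
  g <- genome_sequence(c(c1 = random_dna(5000), c8 = random_dna(5000)))
  h <- make_hmds("c1", 500L, 2500L)
  su <- data.frame(chrom = "c1", pos = c(1000L, 1300L, 1400L))
  sets <- build_linker_core_sets(h, su, g, holdout_chrom = "c8")
  expect_equal(nrow(sets$positives), 3L)
  expect_equal(sets$positives$start, c(950L, 1250L, 1350L))
  # only the 1000/1300 pair exceeds the 150-bp gap: negative at [1100,1200)
  expect_equal(nrow(sets$negatives), 1L)
  expect_equal(sets$negatives$start, 1100L)
  expect_equal(sets$negatives$end, 1200L)
  expect_error(build_linker_core_sets(h, su, g, seq_len = 101L,
                                      holdout_chrom = "c8"), "even")
  # windows crossing the HMD edge are dropped
  su2 <- data.frame(chrom = "c1", pos = c(510L, 2490L))
  sets2 <- build_linker_core_sets(h, su2, g, holdout_chrom = "c8")
  expect_equal(nrow(sets2$positives), 0L)
})

test_that("linker/core sets match brute-force pair enumeration", {
  withr::local_seed(77)
  g <- genome_sequence(c(c1 = random_dna(20000)))
  for (rep in 1:8) {
    h <- make_hmds("c1", 1000L, 19000L)
    su <- data.frame(chrom = "c1",
                     pos = sort(sample(seq(1200L, 18800L, by = 10L), 25)))
    sets <- build_linker_core_sets(h, su, g, holdout_chrom = "none")
    mids <- integer(0)
    for (i in seq_len(nrow(su) - 1)) {
      if (su$pos[i + 1] - su$pos[i] > 150L)
        mids <- c(mids, (su$pos[i] + su$pos[i + 1]) %/% 2L)
    }
    mids <- mids[mids - 50L >= 1000L & mids + 50L <= 19000L]
    expect_equal(sort(sets$negatives$start), sort(mids - 50L))
    expect_equal(nrow(sets$positives), 25L)
  }
})

test_that("HMD-vs-methylated sets respect length, copies and placement", {
  withr::local_seed(55)
  g <- genome_sequence(c(c1 = random_dna(60000), c8 = random_dna(60000)))
  h <- make_hmds(c("c1", "c1"), c(10000L, 30000L), c(12000L, 33500L))
  sets <- build_hmd_vs_methylated_sets(h, g, seed = 9L, holdout_chrom = "c8")
  expect_equal(nrow(sets$positives), 1L)   # only the 2000-bp HMD is < 3 kb
  expect_equal(nrow(sets$negatives), 10L)
  expect_true(all(nchar(sets$negatives$seq) == 2000L))
  # negatives never intersect any HMD (exhaustive check)
  for (i in seq_len(nrow(sets$negatives)))
    expect_equal(overlap_bp(sets$negatives[i, ], h), 0)
  # reproducible from seed
  sets2 <- build_hmd_vs_methylated_sets(h, g, seed = 9L, holdout_chrom = "c8")
  expect_identical(sets$negatives$start, sets2$negatives$start)
})

test_that("training recovers a separable motif and is label-symmetric", {
  withr::local_seed(66)
  pos_seq <- vapply(1:40, function(i) {
    s <- random_dna(60); substr(s, 20, 25) <- "AAAAAA"; s
  }, "")
  neg_seq <- vapply(1:40, function(i) {
    s <- random_dna(60)
    while (grepl("AAAAAA", s)) s <- random_dna(60)
    s
  }, "")
  mkset <- function(p, n) {
    df <- function(x) data.frame(seq = x, chrom = rep("c1", length(x)),
                                 start = seq_along(x), end = seq_along(x) + 60L)
    structure(list(positives = df(p), negatives = df(n),
                   holdout_chrom = "none", n_dropped = 0L),
              class = "labeled_seq_set")
  }
  m <- train_kmer_svm(mkset(pos_seq, neg_seq), k = 6L)
  expect_equal(names(which.max(m$weights)), "AAAAAA")
  # swapping the classes exactly negates weights and bias
  m2 <- train_kmer_svm(mkset(neg_seq, pos_seq), k = 6L)
  expect_identical(m2$weights, -m$weights)
  expect_identical(m2$bias, -m$bias)
  # decision values reproduce w.f(x) + b
  d <- decision_values(m, pos_seq[1:5])
  X <- kmer_features(pos_seq[1:5], 6L)
  expect_equal(d, as.numeric(X %*% m$weights) + m$bias, tolerance = 1e-6)
  expect_identical(decision_values(m2, pos_seq[1:5]), -d)
  # single-class input
  empty <- mkset(pos_seq, character(0))
  expect_error(train_kmer_svm(empty, k = 6L), "single-class")
})

test_that("holdout discipline: test-chromosome sequences never affect weights", {
  withr::local_seed(10)
  base <- data.frame(seq = vapply(1:30, function(i) random_dna(50), ""),
                     chrom = rep(c("c1", "c2"), 15), start = 1:30, end = 1:30 + 50L)
  sets <- structure(list(positives = base[1:15, ], negatives = base[16:30, ],
                         holdout_chrom = "c2", n_dropped = 0L),
                    class = "labeled_seq_set")
  m1 <- train_kmer_svm(sets, k = 3L)
  # scramble every holdout sequence; weights must be bit-identical
  sets2 <- sets
  hold <- sets2$positives$chrom == "c2"
  sets2$positives$seq[hold] <- vapply(seq_len(sum(hold)),
                                      function(i) random_dna(50), "")
  m2 <- train_kmer_svm(sets2, k = 3L)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
})

test_that("score_hmd averages overlapping windows per 20-bp step", {
  g <- genome_sequence(c(c1 = random_dna(1000)))
  h <- make_hmds("c1", 100L, 420L)
  zero <- structure(list(k = 2L, weights = setNames(rep(0, 16),
                                                    colnames(kmer_features("AC", 2))),
                         bias = 1.5, C = 1, normalize = TRUE,
                         revcomp_collapse = FALSE, training_meta = list()),
                    class = "kmer_model")
  sc <- score_hmd(h[1, ], g, zero)
  expect_true(all(sc$score == 1.5))
  # a window-sized HMD has one window; every step inherits its decision
  h1 <- make_hmds("c1", 100L, 200L)
  m <- train_kmer_svm(structure(list(
    positives = data.frame(seq = c("ACACAC", "ACACAA"), chrom = "cX",
                           start = 1:2, end = 7:8),
    negatives = data.frame(seq = c("GTGTGT", "GTGTGG"), chrom = "cX",
                           start = 1:2, end = 7:8),
    holdout_chrom = "none", n_dropped = 0L), class = "labeled_seq_set"),
    k = 2L)
  sc1 <- score_hmd(h1[1, ], g, m)
  expect_equal(length(sc1$decision), 1L)
  expect_true(all(sc1$score == sc1$decision[1]))
  expect_error(score_hmd(h1[1, ], g, m, window = 100L, step = 30L),
               "multiple")
})

test_that("score_hmd matches brute-force window enumeration", {
  withr::local_seed(88)
  g <- genome_sequence(c(c1 = random_dna(3000)))
  m <- train_kmer_svm(structure(list(
    positives = data.frame(seq = vapply(1:10, function(i) random_dna(40), ""),
                           chrom = "cX", start = 1:10, end = 41:50),
    negatives = data.frame(seq = vapply(1:10, function(i) random_dna(40), ""),
                           chrom = "cX", start = 1:10, end = 41:50),
    holdout_chrom = "none", n_dropped = 0L), class = "labeled_seq_set"),
    k = 2L)
  h <- make_hmds("c1", 200L, 200L + 510L)
  sc <- score_hmd(h[1, ], g, m, window = 100L, step = 20L)
  len <- 510L
  wstarts <- seq(0L, len - 100L, by = 20L)
  dec <- decision_values(m, substring(g[["c1"]], 200L + wstarts + 1L,
                                      200L + wstarts + 100L))
  for (j in seq_along(sc$step_start)) {
    a <- sc$step_start[j] - 200L
    ov <- wstarts < a + 20L & wstarts + 100L > a
    expect_equal(sc$score[j], mean(dec[ov]), tolerance = 1e-12)
  }
})

test_that("correlate_scores computes textbook Pearson r and P", {
  g <- genome_sequence(c(c1 = random_dna(1000)))
  h <- make_hmds("c1", 100L, 500L)
  m <- train_kmer_svm(structure(list(
    positives = data.frame(seq = vapply(1:8, function(i) random_dna(40), ""),
                           chrom = "cX", start = 1:8, end = 41:48),
    negatives = data.frame(seq = vapply(1:8, function(i) random_dna(40), ""),
                           chrom = "cX", start = 1:8, end = 41:48),
    holdout_chrom = "none", n_dropped = 0L), class = "labeled_seq_set"),
    k = 2L)
  sc <- score_hmd(h[1, ], g, m)
  # signal = affine transform of the score -> r = 1
  v <- rep(NA_real_, 1000)
  for (j in seq_along(sc$step_start))
    v[(sc$step_start[j] + 1):(sc$step_start[j] + 20)] <- 2 * sc$score[j] + 1
  r1 <- correlate_scores(sc, signal_track(list(c1 = v)))
  expect_equal(r1$r, 1, tolerance = 1e-9)
  # random signal: match cor.test directly
  withr::local_seed(3)
  v2 <- runif(1000)
  r2 <- correlate_scores(sc, signal_track(list(c1 = v2)))
  sig <- vapply(sc$step_start, function(a) mean(v2[(a + 1):(a + 20)]),
                numeric(1))
  ct <- cor.test(sc$score, sig)
  expect_equal(r2$r, unname(ct$estimate))
  expect_equal(r2$p, ct$p.value)
  # zero-variance signal is flagged degenerate
  r3 <- correlate_scores(sc, flat_track(c(c1 = 1000L), 2))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$r))
})

test_that("ROC/PR: perfect separation, null behaviour, Mann-Whitney identity", {
  expect_equal(roc_pr(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))$auc, 1)
  withr::local_seed(19)
  null <- roc_pr(rnorm(1e4), rep(c(1, 0), 5e3))
  expect_lt(abs(null$auc - 0.5), 0.02)
  for (rep in 1:5) {
    sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == 60) next
    u <- wilcox.test(sc[lb == 1], sc[lb == 0], exact = FALSE)$statistic
    expect_equal(roc_pr(sc, lb)$auc, unname(u) / (sum(lb) * sum(1 - lb)),
                 tolerance = 1e-12)
  }
  expect_error(roc_pr(1:3, c(1, 1, 1)), "single-class")
})

test_that("compare_weights ranks and tests as an unpaired Wilcoxon", {
  fake <- function(w) structure(list(k = 3L, weights = w, bias = 0, C = 1,
                                     normalize = TRUE,
                                     revcomp_collapse = FALSE,
                                     training_meta = list()),
                                class = "kmer_model")
  withr::local_seed(29)
  km <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)),
                   1, paste0, collapse = ""))
  wa <- setNames(rnorm(64), km)
  wb <- setNames(rnorm(64), km)
  cw <- compare_weights(fake(wa), fake(wb), top_n = 10L)
  top <- names(sort(wa, decreasing = TRUE))[1:10]
  expect_setequal(cw$top_kmers, top)
  want <- suppressWarnings(wilcox.test(wb[top], wb, exact = FALSE))$p.value
  expect_equal(cw$rank_test_p, want)
  # self-comparison: top group has maximal ranks
  cwself <- compare_weights(fake(wa), fake(wa), top_n = 10L)
  expect_lt(cwself$rank_test_p, 0.001)
  expect_error(compare_weights(fake(wa),
                               structure(list(k = 2L, weights = wa, bias = 0,
                                              revcomp_collapse = FALSE),
                                         class = "kmer_model")), "mismatch")
})

test_that("models serialize and reload losslessly", {
  withr::local_seed(70)
  km <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 2)),
                   1, paste0, collapse = ""))
  m <- structure(list(k = 2L, weights = setNames(rnorm(16), km), bias = 0.3,
                      C = 1, normalize = TRUE, revcomp_collapse = FALSE,
                      training_meta = list(n_pos = 5L, n_neg = 6L,
                                           holdout_chrom = "c8",
                                           iterations = 10L,
                                           converged = TRUE)),
                 class = "kmer_model")
  pre <- file.path(withr::local_tempdir(), "model")
  write_kmer_model(m, pre)
  m2 <- read_kmer_model(pre)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$k, m$k)
})
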