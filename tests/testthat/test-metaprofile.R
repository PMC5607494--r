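test_that("select_anchors picks the in-HMD summit nearest each boundary", {
  h <- make_hmds("c1", 1000L, 3000L)
  su <- data.frame(chrom = "c1", pos = c(1100L, 2000L, 2900L))
  tss <- data.frame(chrom = "c1", start = 1090L, end = 1091L, strand = "+")
  an <- select_anchors(h, su, tss)
  expect_equal(an$pos[an$side == "5p"], 1100L)
  expect_equal(an$pos[an$side == "3p"], 2900L)
  expect_equal(an$interior, c("+", "-"))
  # HMD without summits contributes nothing
  h2 <- make_hmds("c1", c(1000L, 5000L), c(3000L, 6000L))
  expect_equal(nrow(select_anchors(h2, su, tss)), 2L)
  # no TSS within 1 kb: anchor dropped
  expect_equal(nrow(select_anchors(h, su,
    data.frame(chrom = "c1", start = 8000L, end = 8001L, strand = "+"))), 0L)
})

test_that("select_anchors agrees with brute-force nearest-summit search", {
  withr::local_seed(17)
  for (rep in 1:10) {
    starts <- sort(sample(seq(0L, 8000L, by = 1000L), 4)) + 100L
    h <- make_hmds("c1", starts, starts + 800L)
    su <- data.frame(chrom = "c1", pos = sort(sample(0:8900, 60)))
    tss <- data.frame(chrom = "c1", start = sample(0:8900, 15),
                      end = 0L, strand = sample(c("+", "-"), 15, TRUE))
    tss$end <- tss$start + 1L
    an <- select_anchors(h, su, tss)
    for (i in seq_len(nrow(h))) {
      sp <- su$pos[su$pos >= h$start[i] & su$pos < h$end[i]]
      arows <- an[an$hmd_id == h$hmd_id[i], ]
      d_hmd <- min(pmax(h$start[i] - tss$start, tss$start - (h$end[i] - 1L), 0L))
      if (!length(sp) || d_hmd > 1000) { expect_equal(nrow(arows), 0L); next }
      for (end_ in c("left", "right")) {
        b <- if (end_ == "left") h$boundary_cpg_5p[i] else h$boundary_cpg_3p[i]
        nearest <- sp[which.min(abs(sp - b))]
        row <- arows[arows$interior == (if (end_ == "left") "+" else "-"), ]
        expect_equal(row$pos, nearest)
        # orientation comes from the TSS nearest the anchor
        near_t <- tss$strand[which.min(abs(tss$start - nearest))]
        want_side <- if (near_t == row$interior) "5p" else "3p"
        # ties in TSS distance can flip strand choice; only check when unique
        dd <- sort(abs(tss$start - nearest))
        if (length(dd) < 2 || dd[1] != dd[2])
          expect_equal(row$side, want_side)
      }
    }
  }
})

test_that("metaprofile extracts, orients and averages windows", {
  ramp <- signal_track(list(c1 = as.numeric(0:999)))
  a <- data.frame(chrom = "c1", pos = 500L, side = "5p", orientation = "+",
                  interior = "+", hmd_id = 1L)
  p <- metaprofile(ramp, a, flank = 100L, orient = TRUE)
  expect_equal(p$mean, as.numeric(400:600))
  expect_true(all(p$n == 1L))
  # mirror anchors on a symmetric track: flipped window equals unflipped
  a2 <- rbind(a, transform(a, interior = "-"))
  p2 <- metaprofile(ramp, a2, flank = 100L, orient = TRUE)
  expect_equal(p2$mean, rep(500, 201))  # ramp + reversed ramp averages flat
  # chromosome edges and NA positions are excluded from n
  short <- signal_track(list(c1 = c(NA, 1, 2, 3)))
  a3 <- data.frame(chrom = "c1", pos = 1L, side = "5p", orientation = "+",
                   interior = "+", hmd_id = 1L)
  p3 <- metaprofile(short, a3, flank = 2L, orient = FALSE)
  expect_equal(p3$n, c(0L, 0L, 1L, 1L, 1L))
  expect_true(is.na(p3$mean[1]))
  expect_error(metaprofile(ramp, a[0, ], flank = 10L), "no anchors")
})

test_that("metaprofile is linear in the track", {
  withr::local_seed(23)
  x <- runif(2000); y <- runif(2000)
  tx <- signal_track(list(c1 = x)); ty <- signal_track(list(c1 = y))
  tz <- signal_track(list(c1 = 2 * x + 3 * y))
  a <- data.frame(chrom = "c1", pos = sample(300:1700, 20), side = "5p",
                  orientation = "+",
                  interior = sample(c("+", "-"), 20, TRUE), hmd_id = 1:20)
  pz <- metaprofile(tz, a, flank = 200L)
  px <- metaprofile(tx, a, flank = 200L)
  py <- metaprofile(ty, a, flank = 200L)
  expect_equal(pz$mean, 2 * px$mean + 3 * py$mean, tolerance = 1e-12)
})

test_that("feature tracks mark k-mers, SNP rates and point counts", {
  g <- genome_sequence(c(c1 = "GCTAACGCTAAC"))
  kt <- kmer_occurrence_track(g, "GCTAAC")
  expect_equal(which(kt$values$c1 == 1) - 1L, c(0L, 6L))
  expect_error(kmer_occurrence_track(g, "GCTANC"), "ACGT")
  # overlapping matches are all counted
  g2 <- genome_sequence(c(c1 = "AAAA"))
  expect_equal(sum(kmer_occurrence_track(g2, "AA")$values$c1), 3)
  snps <- data.frame(chrom = "c1", pos = c(10L, 20L))
  sr <- snp_rate_track(snps, c(c1 = 40L), binsize = 10L)
  expect_equal(sr$values$c1[11], 0.1)
  expect_equal(sr$values$c1[21], 0.1)
  expect_equal(sr$values$c1[35], 0)
  tss <- data.frame(chrom = "c1", start = c(5L, 5L, 9L))
  ct <- count_track(tss, c(c1 = 12L))
  expect_equal(ct$values$c1, c(0, 0, 0, 0, 0, 2, 0, 0, 0, 1, 0, 0))
})

test_that("boundary metaprofiles on synthetic data show the expected anatomy", {
  ds <- small_dataset()
  lens <- chrom_lengths(ds$genome)
  hm <- call_hmds(ds$meth)
  cov <- cut_coverage(shift_cuts(ds$cuts, 50L, lens), lens)
  su <- call_summits(cov, min_separation = 100L)
  an <- select_anchors(hm, su, ds$tss)
  a5 <- an[an$side == "5p", ]
  expect_gt(nrow(a5), 5)
  dn <- metaprofile(cov, a5)
  # global maximum at the anchor, next intra-HMD linker ~boundary_gap away
  expect_equal(dn$offset[which.max(dn$mean)], 0L)
  gap <- boundary_linker_gap(dn)
  expect_lt(abs(gap - ds$config$boundary_gap_5p), 15)
  # TSSs pile up at the 5' boundary linker
  tp <- metaprofile(count_track(ds$tss, lens, smooth_bw = 21L), a5)
  expect_lt(abs(tp$offset[which.max(tp$mean)]), 15)
})
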