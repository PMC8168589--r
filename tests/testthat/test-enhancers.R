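mk_track <- function(L = 1e6, bin = 1e4, value = 0, chrom = "chr1") {
  starts <- seq(0, L - bin, by = bin)
  signal_track(chrom, starts, starts + bin, rep_len(value, length(starts)))
}

test_that("stitching excludes TSS-contained peaks, merges across the gap, sums signal", {
  sig <- mk_track(value = 2)
  tss <- intervals("chr1", 49950, 50050)

  # a peak fully inside TSS +/- 2 kb is removed before stitching
  peaks <- intervals("chr1", c(49500, 100e3, 111e3), c(50500, 101e3, 112e3))
  st <- stitch_and_score(peaks, sig, tss = tss, stitch_gap = 12500)
  expect_equal(nrow(st), 1)           # the two distant peaks stitched
  expect_equal(st$start, 100e3)
  expect_equal(st$end, 112e3)
  expect_equal(st$n_peaks, 2L)

  # a peak partially overlapping the exclusion window is kept
  peaks2 <- intervals("chr1", c(46500, 200e3), c(50500, 201e3))
  st2 <- stitch_and_score(peaks2, sig, tss = tss, stitch_gap = 12500)
  expect_equal(nrow(st2), 2)

  expect_error(stitch_and_score(intervals("chr1", 49500, 50500), sig,
                                tss = tss), "no peaks survive")

  # gap semantics: 10-kb gap stitches at the 12.5-kb default
  p3 <- intervals("chr1", c(0, 11e3), c(1e3, 12e3))
  st3 <- stitch_and_score(p3, sig, stitch_gap = 12500)
  expect_equal(nrow(st3), 1)
  expect_equal(c(st3$start, st3$end), c(0, 12e3))

  # scores equal brute-force interval sums, with control subtraction floored
  set.seed(17)
  sigv <- mk_track(value = 0)
  sigv$value <- rnorm(nrow(sigv), 5, 2)
  ctl <- mk_track(value = 0)
  ctl$value <- rnorm(nrow(ctl), 4, 2)
  s <- sort(sample(seq(0, 9.4e5, by = 100), 20))
  peaks <- intervals("chr1", s, s + sample(2e3:2e4, 20, TRUE))
  st4 <- stitch_and_score(peaks, sigv, control = ctl, stitch_gap = 12500)
  for (k in seq_len(nrow(st4))) {
    orc <- oracle_region_sum(sigv, ctl, "chr1", st4$start[k], st4$end[k], 1e4)
    expect_equal(st4$score[k], orc, tolerance = 1e-9)
  }
  expect_equal(sort(st4$rank), seq_len(nrow(st4)))
  expect_equal(st4$rank[which.max(st4$score)], 1L)
})

test_that("the super-enhancer cutoff selects outliers and is scale invariant", {
  r <- se_cutoff(c(1, 1, 1, 1, 100))
  expect_equal(r$n_se, 1L)
  expect_equal(which(r$is_se), 5L)

  # perfectly linear curve: slope never drops below one, no super-enhancers
  lin <- se_cutoff(seq(1, 10))
  expect_lte(lin$n_se, 1L)

  # geometric scores against the exhaustive-scan oracle
  for (r_ in c(1.5, 2, 3)) {
    sc <- r_^(1:20)
    expect_equal(se_cutoff(sc)$n_se, oracle_se_cutoff(sc))
  }

  # scale invariance
  sc <- c(rexp(30), 50, 80)
  base <- se_cutoff(sc)$is_se
  for (k in c(0.1, 10))
    expect_equal(se_cutoff(sc * k)$is_se, base)

  expect_warning(r0 <- se_cutoff(rep(2, 5)), "all scores equal")
  expect_equal(r0$n_se, 0L)
  expect_error(se_cutoff(c(1, 2)), "at least 3")
})

test_that("group stratification forms equal cohorts with the remainder in the weakest groups", {
  mk <- function(scores) {
    structure(data.frame(chrom = "chr1", start = seq_along(scores) * 1e4,
                         end = seq_along(scores) * 1e4 + 1e3,
                         n_peaks = 1L, peak_ids = "p",
                         score = scores,
                         rank = rank(-scores, ties.method = "first"),
                         group = NA_character_),
              class = c("stitched_enhancers", "data.frame"))
  }
  # 9 non-SE + 1 outlier SE: three cohorts of 3, strongest labeled G3
  e <- stratify_groups(mk(c(9:1, 1000)))
  expect_equal(e$group[e$score == 1000], "SE")
  expect_equal(as.vector(table(e$group)[c("G1", "G2", "G3")]), c(3L, 3L, 3L))
  expect_equal(e$group[e$score %in% 7:9], rep("G3", 3))
  expect_equal(e$group[e$score %in% 1:3], rep("G1", 3))

  # 10 non-SE: sizes (G3, G2, G1) = (3, 3, 4)
  e2 <- stratify_groups(mk(c(10:1, 1000)))
  expect_equal(as.vector(table(e2$group)[c("G1", "G2", "G3")]), c(4L, 3L, 3L))

  expect_error(stratify_groups(mk(c(1, 2, 1000)), n_groups = 3),
               "fewer non-SE")
})

test_that("insulation composition stratifies positive regions and applies group priority", {
  s <- c(-1, 0.05, -1, 0.15, -1, 0.25, -1, 0.4, -1)
  tr <- toy_track(s)
  enh <- structure(data.frame(chrom = "chrT",
                              start = c(5 * 25e3, 7 * 25e3),
                              end = c(6 * 25e3, 8 * 25e3),
                              n_peaks = 1L, peak_ids = "p", score = 1,
                              rank = 1:2,
                              group = c("G1", "SE")),
                   class = c("stitched_enhancers", "data.frame"))
  comp <- insulation_composition(tr, enh)
  expect_equal(unname(comp$table["0-0.1", "NoEnh"]), 1L)
  expect_equal(unname(comp$table["0.1-0.2", "NoEnh"]), 1L)
  expect_equal(unname(comp$table["0.2-0.3", "G1"]), 1L)
  expect_equal(unname(comp$table[">0.3", "SE"]), 1L)
  expect_true(all(abs(rowSums(comp$proportions) - 1) < 1e-12))
  expect_equal(sum(comp$genome_share), 1)

  # a region overlapping both an SE and a G1 enhancer counts as SE
  enh2 <- enh
  enh2$start <- c(7 * 25e3, 7 * 25e3)
  enh2$end <- c(8 * 25e3, 8 * 25e3)
  comp2 <- insulation_composition(tr, enh2)
  expect_equal(unname(comp2$table[">0.3", "SE"]), 1L)
  expect_equal(unname(comp2$table[">0.3", "G1"]), 0L)

  # without enhancers everything is NoEnh
  comp3 <- insulation_composition(tr, NULL)
  expect_equal(sum(comp3$table[, "NoEnh"]), 4L)
  expect_equal(sum(comp3$table[, colnames(comp3$table) != "NoEnh"]), 0L)
})

test_that("signal metaplots resample kernels around features faithfully", {
  # constant track -> flat metaplot at the constant
  tr <- mk_track(L = 2e6, value = 3.5)
  f <- intervals("chr1", 1e6, 1e6 + 1e4)
  mp <- signal_metaplot(tr, f, flank = 1e5)
  expect_true(all(abs(mp$mean - 3.5) < 1e-12))
  expect_error(signal_metaplot(tr, f, flank = 1.5e4), "multiple")

  # single feature: metaplot equals the feature's own binned profile
  tr2 <- mk_track(L = 2e6)
  tr2$value <- seq_len(nrow(tr2))
  mp2 <- signal_metaplot(tr2, f, flank = 5e4)
  expect_equal(mp2$mean, as.numeric(mp2$matrix[1, ]))

  # Gaussian kernels at 50 features: maximum at the center, mean matches
  # the analytic kernel average within 5%
  set.seed(23)
  L <- 20e6; bin <- 1e4; sd_k <- 3e4; h <- 8
  centers <- round(seq(3e5, L - 3e5, length.out = 50) / 500) * 500
  starts <- seq(0, L - bin, by = bin)
  x <- starts + bin / 2
  v <- rep(0, length(x))
  for (cc in centers) v <- v + h * exp(-(x - cc)^2 / (2 * sd_k^2))
  tr3 <- signal_track("chr1", starts, starts + bin, v)
  fs <- intervals("chr1", centers - 500, centers + 500)
  mp3 <- signal_metaplot(tr3, fs, flank = 1e5)
  ctr <- order(abs(mp3$offsets))[1:2]
  expect_true(which.max(mp3$mean) %in% ctr)
  analytic <- h * exp(-(mp3$offsets)^2 / (2 * sd_k^2))
  central <- abs(mp3$offsets) < 2.5 * sd_k
  expect_lt(max(abs(mp3$mean[central] - analytic[central]) / h), 0.05)
})

test_that("graded synthetic enhancer signal is recovered by ROSE ranking", {
  g <- synth_data("post_zga_enhancers", n = 5e5)
  tracks <- generate_signal_tracks(g$truth, seed = 7)

  st <- stitch_and_score(tracks$peaks, tracks$signal, tss = tracks$tss)
  expect_false(any(grepl("tss_decoy", st$peak_ids)))

  st <- stratify_groups(st)
  # map each stitched region to its truth group by overlap with enhancers
  truth <- g$truth$enhancers
  got <- character(0); want <- character(0)
  for (k in seq_len(nrow(st))) {
    sel <- truth$chrom == st$chrom[k] & truth$center >= st$start[k] - 2e4 &
      truth$center < st$end[k] + 2e4
    if (sum(sel) != 1) next
    got <- c(got, st$group[k]); want <- c(want, truth$group[sel])
  }
  expect_gt(length(got), 0.9 * nrow(truth))
  expect_gte(mean(got == want), 0.95)

  # noise-free rendering: stitched scores reproduce analytic kernel sums
  tracks0 <- generate_signal_tracks(g$truth, noise_sd = 0, seed = 7,
                                    n_tss_decoys = 0)
  st0 <- stitch_and_score(tracks0$peaks, tracks0$signal)
  one <- st0[which(st0$n_peaks == 1L)[1], ]
  kern_sum <- function(center, height, s, e, bin = 1e4, sd_k = 15e3) {
    starts <- seq(floor(s / bin) * bin, ceiling(e / bin) * bin - bin, by = bin)
    x <- starts + bin / 2
    ov <- pmin(e, starts + bin) - pmax(s, starts)
    sum(height * exp(-(x - center)^2 / (2 * sd_k^2)) * ov / bin)
  }
  tg <- tracks0$truth_groups
  sel <- tg$chrom == one$chrom & abs(tg$center - (one$start + one$end) / 2) < 2e4
  h <- c(G1 = 2, G2 = 4, G3 = 8)[[tg$group[sel][1]]]
  expect_equal(one$score, kern_sum(tg$center[sel][1], h, one$start, one$end),
               tolerance = 1e-6)
})

test_that("strong enhancers sit in small contact domains with higher central insulation", {
  g <- synth_data("post_zga_enhancers")
  trs <- preset_tracks("post_zga_enhancers", 25e3, c(50e3, 100e3, 200e3))
  truth <- g$truth$enhancers
  central <- function(groups) {
    vals <- c()
    for (ch in names(trs)) {
      e <- truth[truth$chrom == ch & truth$group %in% groups, ]
      if (nrow(e) == 0) next
      h <- feature_insulation_heatmap(
        trs[[ch]], intervals(ch, e$center - 1, e$center + 1), flank = 50e3)
      vals <- c(vals, h[, 3])
    }
    mean(vals, na.rm = TRUE)
  }
  expect_gt(central(c("SE", "G3")), central(c("G1", "G2")))
})
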