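test_that("bin_pairs assigns floor-division bins, enforces standard resolutions, conserves counts", {
  asm <- genome_assembly("chr1", 1e6)
  p <- data.frame(chrom1 = "chr1", pos1 = 26000, chrom2 = "chr1", pos2 = 74000)
  m <- bin_pairs(p, asm, 25e3)[["chr1"]]
  expect_equal(m$counts[2, 3], 1)   # bins 1 and 2 (0-based) -> rows 2, 3
  expect_equal(m$counts[3, 2], 1)
  expect_equal(sum(m$counts), 2)

  expect_error(bin_pairs(p, asm, 13e3), "non-standard resolution")
  expect_silent(bin_pairs(p, asm, 13e3, allow_any_resolution = TRUE))

  # count conservation over random pairs, including the diagonal
  set.seed(5)
  n <- 1000
  pos1 <- sample(0:(1e6 - 1), n, TRUE)
  pos2 <- sample(0:(1e6 - 1), n, TRUE)
  pr <- data.frame(chrom1 = "chr1", pos1 = pmin(pos1, pos2),
                   chrom2 = "chr1", pos2 = pmax(pos1, pos2))
  m <- bin_pairs(pr, asm, 25e3)[["chr1"]]
  ut <- m$counts[upper.tri(m$counts)]
  expect_equal(sum(ut) + sum(diag(m$counts)), n)
  expect_equal(attr(bin_pairs(pr, asm, 25e3), "n_retained"), n)
  expect_true(isSymmetric(m$counts))

  # min_dist and trans filtering are tallied
  asm2 <- genome_assembly(c("chr1", "chr2"), c(1e6, 1e6))
  pr2 <- data.frame(chrom1 = c("chr1", "chr1"), pos1 = c(0, 0),
                    chrom2 = c("chr1", "chr2"), pos2 = c(500, 500))
  got <- bin_pairs(pr2, asm2, 25e3, min_dist = 1000)
  expect_equal(attr(got, "n_trans"), 1L)
  expect_equal(attr(got, "n_short"), 1L)
  expect_equal(attr(got, "n_retained"), 0L)
})

test_that("iterative correction equalizes marginals, masks empty bins, matches Sinkhorn", {
  # constant matrix: marginals equal exactly, output proportional to input
  cm <- make_fixture_matrix("constant", n_bins = 10, value = 3)
  cm$balanced <- FALSE
  b <- balance_matrix(cm)
  expect_true(all(abs(rowSums(b$counts) - mean(rowSums(b$counts))) < 1e-9))
  expect_true(max(abs(b$counts / b$counts[1, 1] - 1)) < 1e-9)

  # 3x3 worked example against an independent Sinkhorn oracle
  x <- matrix(c(0, 2, 2, 2, 0, 6, 2, 6, 0), 3, 3)
  cm <- structure(list(chrom = "c", resolution = 25e3, counts = x,
                       mask = rep(TRUE, 3), weights = NULL, balanced = FALSE),
                  class = "contact_matrix")
  b <- balance_matrix(cm, tol = 1e-9)
  marg <- rowSums(b$counts)
  expect_true(max(abs(marg / mean(marg) - 1)) < 1e-6)
  orc <- oracle_sinkhorn(x)
  expect_equal(b$counts / mean(rowSums(b$counts)), orc, tolerance = 1e-6)

  # a zero row is masked, the rest balance
  x2 <- matrix(rexp(25), 5, 5); x2 <- x2 + t(x2)
  x2[3, ] <- 0; x2[, 3] <- 0
  cm2 <- structure(list(chrom = "c", resolution = 25e3, counts = x2,
                        mask = rep(TRUE, 5), weights = NULL, balanced = FALSE),
                   class = "contact_matrix")
  b2 <- balance_matrix(cm2, mask_frac = 0.1)
  expect_false(b2$mask[3])
  expect_true(all(is.na(b2$counts[3, ])))
  marg <- rowSums(b2$counts[b2$mask, b2$mask])
  expect_true(max(abs(marg / mean(marg) - 1)) < 1e-5)

  # all-empty matrix errors
  cm0 <- structure(list(chrom = "c", resolution = 25e3,
                        counts = matrix(0, 4, 4), mask = rep(TRUE, 4),
                        weights = NULL, balanced = FALSE),
                   class = "contact_matrix")
  expect_error(balance_matrix(cm0), "too sparse")

  # balancing an already-balanced matrix is a near-identity
  b3 <- balance_matrix(b)
  expect_equal(b3$counts, b$counts, tolerance = 1e-5)
})

test_that("observed/expected divides by per-diagonal means and propagates undefined entries", {
  # distance-only matrix gives O/E of exactly 1
  n <- 12
  f <- function(d) 10 / (1 + d)
  x <- outer(1:n, 1:n, function(i, j) f(abs(i - j)))
  cm <- structure(list(chrom = "c", resolution = 25e3, counts = x,
                       mask = rep(TRUE, n), weights = rep(1, n),
                       balanced = TRUE), class = "contact_matrix")
  r <- observed_over_expected(cm)
  expect_true(max(abs(r$oe - 1)) < 1e-12)

  # random matrix against the per-diagonal oracle; diagonal means are 1
  cm <- random_cm(10, seed = 9)
  r <- observed_over_expected(cm)
  orc <- oracle_oe(cm$counts)
  expect_equal(r$oe, orc$oe, tolerance = 1e-12)
  expect_equal(r$expected$value, orc$expected, tolerance = 1e-12)
  for (d in 1:5)
    expect_equal(mean(r$oe[cbind(1:(10 - d), (1 + d):10)]), 1,
                 tolerance = 1e-12)

  # masked bins yield undefined rows/columns
  cm <- random_cm(10, mask_k = 2, seed = 10)
  r <- observed_over_expected(cm)
  expect_true(all(is.na(r$oe[!cm$mask, ])))
})

test_that("contact decay bins distances, integrates to one, recovers power-law slopes", {
  p <- data.frame(chrom1 = "chr1", pos1 = rep(0, 50), chrom2 = "chr1",
                  pos2 = rep(1e5, 50))
  dc <- contact_decay(p, min_dist = 1e3)
  expect_equal(sum(dc$prob), 1)
  expect_equal(sum(dc$count[dc$lo <= 1e5 & dc$hi > 1e5]), 50)

  # order invariance
  set.seed(2)
  pr <- data.frame(chrom1 = "chr1", pos1 = 0,
                   chrom2 = "chr1", pos2 = sample(2e3:2e6, 5000))
  expect_equal(contact_decay(pr), contact_decay(pr[sample(5000), ]))

  expect_error(contact_decay(p, min_dist = 1e7), "no cis pairs")

  # slope of a pure power-law sample: P(s) ~ s^-1 over 10 kb - 10 Mb
  set.seed(3)
  u <- runif(1e6)
  d <- 1e4 * (1e7 / 1e4)^u
  pr <- data.frame(chrom1 = "chr1", pos1 = 0, chrom2 = "chr1", pos2 = d)
  dc <- contact_decay(pr, min_dist = 1e4)
  sl <- decay_slope(dc, 1.2e4, 8e6)
  expect_lt(abs(sl - (-1)), 0.1)
})

test_that("downsampling is exact, seeded, and unbiased", {
  set.seed(1)
  pr <- data.frame(chrom1 = "chr1", pos1 = 1:200, chrom2 = "chr1",
                   pos2 = 1:200 + 1000)
  expect_error(downsample_pairs(pr, 201, 1), "cannot sample")
  expect_equal(sort(downsample_pairs(pr, 200, 1)$pos1), pr$pos1)

  a <- downsample_pairs(pr, 50, seed = 99)
  b <- downsample_pairs(pr, 50, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)

  # per-record inclusion frequency ~ Binomial(reps, 1/2)
  reps <- 1000
  counts <- integer(200)
  for (k in seq_len(reps)) {
    idx <- downsample_pairs(pr, 100, seed = k)$pos1
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(abs(counts / reps - 0.5) < 0.06))
})

test_that("matrix text serialization round-trips counts, mask, and weights", {
  asm <- genome_assembly("chr1", 1e6)
  set.seed(4)
  pr <- data.frame(chrom1 = "chr1", pos1 = sample(0:9e5, 500, TRUE),
                   chrom2 = "chr1", pos2 = sample(0:9e5, 500, TRUE))
  pr <- canonicalize_pairs(pr, asm)
  m <- bin_pairs(pr, asm, 50e3)[["chr1"]]
  b <- balance_matrix(m)
  f <- withr::local_tempfile()
  write_matrix(b, f)
  r <- read_matrix(f)
  expect_equal(r$counts, b$counts, tolerance = 1e-12)
  expect_equal(r$mask, b$mask)
  expect_equal(r$weights, b$weights, tolerance = 1e-12)
  expect_true(r$balanced)
})
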