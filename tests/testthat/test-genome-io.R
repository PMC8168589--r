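test_that("chrom.sizes parsing preserves order, tags namespaces, rejects bad input", {
  f <- withr::local_tempfile()
  writeLines(c("25\t38000000", "2L\t23500000", "chr1\t1000000"), f)
  asm <- read_chrom_sizes(f, namespace_rule = list(
    spikein = c("2L", "2R", "3L", "3R", "4D", "XD", "YD")))
  expect_equal(asm$chrom, c("25", "2L", "chr1"))
  expect_equal(asm$namespace, c("target", "spikein", "target"))
  expect_equal(asm$length[1], 38e6)

  # serialization round-trip keeps order
  f2 <- withr::local_tempfile()
  write_chrom_sizes(asm, f2)
  expect_equal(read_chrom_sizes(f2)$chrom, asm$chrom)

  writeLines(c("chr1\t100", "chr1\t200"), f)
  expect_error(read_chrom_sizes(f), "duplicate.*line 2")
  writeLines(c("chr1\t0"), f)
  expect_error(read_chrom_sizes(f), "line 1")
  writeLines(c("chr1"), f)
  expect_error(read_chrom_sizes(f), "malformed")
})

test_that("pairs records are canonicalized, filtered, and round-trip through .pairs files", {
  asm <- genome_assembly(c("chr1", "chr2", "2L"), c(1e6, 1e6, 5e5),
                         namespace = c("target", "target", "spikein"))
  p <- data.frame(chrom1 = "chr2", pos1 = 500, chrom2 = "chr1", pos2 = 100,
                  strand1 = "+", strand2 = "-")
  cp <- canonicalize_pairs(p, asm)
  expect_equal(cp$chrom1, "chr1")
  expect_equal(cp$pos1, 100)
  expect_equal(cp$chrom2, "chr2")
  expect_equal(cp$strand1, "-")

  # namespace filter drops records touching spike-in chromosomes
  set.seed(1)
  n <- 10
  chroms <- c(rep("chr1", 7), rep("2L", 3))
  pr <- data.frame(chrom1 = chroms, pos1 = sample(1e5, n),
                   chrom2 = chroms, pos2 = sample(1e5, n) + 2e5,
                   strand1 = "+", strand2 = "+")
  f <- withr::local_tempfile(fileext = ".pairs")
  write_pairs(pr, f, asm)
  got <- read_pairs(f, asm, namespace_filter = "target")
  expect_equal(nrow(got), 7)
  expect_equal(attr(got, "n_dropped_namespace"), 3L)

  # read -> write -> read preserves the coordinate multiset (1,000 records)
  set.seed(42)
  n <- 1000
  pos1 <- sample(0:(1e6 - 1), n, replace = TRUE)
  pos2 <- sample(0:(1e6 - 1), n, replace = TRUE)
  pr <- canonicalize_pairs(
    data.frame(chrom1 = sample(c("chr1", "chr2"), n, TRUE), pos1 = pos1,
               chrom2 = "chr2", pos2 = pos2,
               strand1 = ".", strand2 = "."), asm)
  f1 <- withr::local_tempfile(fileext = ".pairs.gz")
  write_pairs(pr, f1, asm)
  r1 <- read_pairs(f1, asm)
  key <- function(x) sort(paste(x$chrom1, x$pos1, x$chrom2, x$pos2))
  expect_identical(key(r1), key(pr))

  # unknown chromosomes: hard error by default, counted skip on request
  writeLines(c("## pairs format v1.0", "r1 chrUn 10 chr1 20 + +"), f1 <- withr::local_tempfile())
  expect_error(read_pairs(f1, asm), "unknown chromosome")
  expect_warning(got <- read_pairs(f1, asm, on_unknown = "skip"), "skipped 1")
  expect_equal(nrow(got), 0)

  # out-of-bounds position
  writeLines(c("r1 chr1 999999999 chr1 20 + +"), f1)
  expect_error(read_pairs(f1, asm), "outside chromosome")
})

test_that("BED and bedGraph readers validate coordinates and detect bin size", {
  asm <- genome_assembly("chr1", 1e6)
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t100\tpeak1\t5\t+", f)
  iv <- read_intervals(f, "bed", asm)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 100)
  expect_equal(iv$name, "peak1")
  expect_equal(iv$score, 5)
  expect_equal(iv$strand, "+")

  writeLines("chr1\t200\t100", f)
  expect_error(read_intervals(f, "bed", asm), "line 1")
  writeLines("chrNo\t0\t100", f)
  expect_error(read_intervals(f, "bed", asm), "unknown chromosome")

  writeLines(sprintf("chr1\t%d\t%d\t%.1f", seq(0, 40000, 10000),
                     seq(10000, 50000, 10000), rnorm(5)), f)
  tr <- read_intervals(f, "bedgraph", asm)
  expect_s3_class(tr, "signal_track")
  expect_equal(attr(tr, "bin_size"), 10000)

  # writer round-trips
  f2 <- withr::local_tempfile()
  write_intervals(tr, f2)
  tr2 <- read_intervals(f2, "bedgraph", asm)
  expect_equal(tr2$value, tr$value, tolerance = 1e-12)
})

test_that("merge_intervals honors the inclusive gap rule and is idempotent", {
  x <- intervals("chr1", c(0, 125e3), c(100e3, 200e3))
  m <- merge_intervals(x, max_gap = 50e3)   # 25-kb gap: within 50 kb
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0)
  expect_equal(m$end, 200e3)

  x2 <- intervals("chr1", c(0, 200e3), c(100e3, 300e3))
  expect_equal(nrow(merge_intervals(x2, 50e3)), 2)   # 100-kb gap stays split

  # exactly at the gap merges (inclusive "within")
  x3 <- intervals("chr1", c(0, 150e3), c(100e3, 200e3))
  expect_equal(nrow(merge_intervals(x3, 50e3)), 1)

  expect_equal(nrow(merge_intervals(x[0, ], 50e3)), 0)

  # idempotence + agreement with the naive fixpoint oracle on random sets
  for (trial in 1:20) {
    set.seed(trial)
    n <- 100
    s <- sample(0:(1e6), n, replace = TRUE)
    x <- intervals(sample(c("chr1", "chr2"), n, TRUE), s,
                   s + sample(1e3:5e4, n, TRUE))
    gap <- sample(c(0, 1e3, 2e4), 1)
    m1 <- merge_intervals(x, gap)
    expect_equal(merge_intervals(m1, gap)[, c("chrom", "start", "end")],
                 m1[, c("chrom", "start", "end")])
    orc <- oracle_merge(x, gap)
    expect_equal(m1$start, orc$start)
    expect_equal(m1$end, orc$end)
    expect_true(sum(m1$end - m1$start) >= 0)
    expect_lte(nrow(m1), n)
  }
})

test_that("subtract_blacklist drops or trims overlaps and matches the all-pairs oracle", {
  fl <- intervals("chr1", 1.0e6, 1.2e6)
  bl <- intervals("chr1", 1.1e6, 1.3e6)
  expect_equal(nrow(subtract_blacklist(fl, bl, "drop")), 0)

  clean <- intervals("chr1", 0, 1e5)
  expect_equal(nrow(subtract_blacklist(clean, bl, "drop")), 1)
  expect_equal(subtract_blacklist(clean, clean[0, ], "drop"), clean)

  tr <- subtract_blacklist(fl, bl, "trim")
  expect_equal(tr$start, 1.0e6)
  expect_equal(tr$end, 1.1e6)

  for (trial in 1:20) {
    set.seed(100 + trial)
    x <- intervals("chr1", s <- sample(0:9e5, 30), s + sample(1e3:5e4, 30, TRUE))
    b <- intervals("chr1", s2 <- sample(0:9e5, 10), s2 + sample(1e3:1e5, 10, TRUE))
    got <- subtract_blacklist(x, b, "drop")
    orc <- oracle_drop_overlapping(x, b)
    expect_equal(got$start, orc$start)
    expect_equal(got$end, orc$end)
  }
})
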