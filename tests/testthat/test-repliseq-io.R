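test_that("bedGraph round trip preserves records and values", {
  g <- genomeGrid(c(chr1 = 3L, chr2 = 2L))
  tp <- timingProfile(list(chr1 = c(12.5, 100, 3.25), chr2 = c(0.5, 7)),
                      g, "observed")
  p <- tempfile(fileext = ".bedgraph")
  writeBedGraph(tp, p)
  back <- readBedGraph(p)
  expect_length(back, 5L)
  expect_equal(S4Vectors::mcols(back)$score, c(12.5, 100, 3.25, 0.5, 7))
  expect_equal(GenomicRanges::start(back), c(1, 1001, 2001, 1, 1001))
  # and a second round trip is the identity
  p2 <- tempfile(fileext = ".bedgraph")
  writeBedGraph(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("bedGraph dialect quirks are handled", {
  p <- tmpTextFile(c(
    "track type=bedGraph name=\"toy\"",
    "# a comment",
    "chr1\t0\t1000\t5",
    "chr1\t1000\t2000\t6"))
  gr <- readBedGraph(p)
  expect_length(gr, 2L)
  expect_equal(S4Vectors::mcols(gr)$score, c(5, 6))
})

test_that("overlaps are normalized last-writer-wins with a warning", {
  p <- tmpTextFile(c(
    "chr1\t0\t2000\t1",
    "chr1\t1000\t3000\t9"))
  expect_warning(gr <- readBedGraph(p), "last-writer-wins")
  # the overlapped middle kb takes the later record's value
  v <- binTrackToGrid(gr, genomeGrid(c(chr1 = 3L)), "mean")$chr1
  expect_equal(v, c(1, 9, 9))
})

test_that("malformed bedGraph lines are rejected with line numbers", {
  expect_error(readBedGraph(tmpTextFile(c(
    "chr1\t0\t1000\t5", "chr1\t5000\t4000\t2"))), "line 2")
  expect_error(readBedGraph(tmpTextFile(c(
    "chr1\t0\t1000\tfoo"))), "line 1")
  expect_error(readBedGraph(tmpTextFile(c(
    "track something", "chr1\t0\t1000"))), "line 2")
  expect_error(readBedGraph(tempfile()), "not found")
})

test_that("BED intervals read with class labels from patterns or columns", {
  p <- tmpTextFile(c(
    "chr1\t0\t5000\tFRA3B",
    "chr1\t9000\t12000\tgene_X",
    "chr2\t0\t2000\tFRA16D"), ext = ".bed")
  gr <- readBedIntervals(p, classMap = c(fragile = "^FRA", genic = "^gene"))
  expect_equal(S4Vectors::mcols(gr)$class, c("fragile", "genic", "fragile"))
  # 5th column as explicit class
  p2 <- tmpTextFile(c("chr1\t0\t1000\tx\tcommon"), ext = ".bed")
  expect_equal(S4Vectors::mcols(readBedIntervals(p2))$class, "common")
  expect_error(readBedIntervals(tmpTextFile("chr1\t100\t50\tz")), "line 1")
})

test_that("wavelet signal converts to minutes with the x6 rescaling", {
  g <- genomeGrid(c(chr1 = 3L))
  mk <- function(vals) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 1001, 2001), width = 1000),
    score = vals)
  # orientation anchors: 100 -> 0 min (earliest), 0 -> 600 min (latest)
  tp <- encodeSignalToTiming(mk(c(100, 0, 50)), g)
  expect_equal(replicationTimes(tp)$chr1, c(0, 600, 300))
  # coverage-weighted mean: 40 and 80 on equal spans -> 60 -> 240 min
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 501), width = 500), score = c(40, 80))
  g1 <- genomeGrid(c(chr1 = 1L))
  expect_equal(replicationTimes(encodeSignalToTiming(gr, g1))$chr1, 240)
  # uncovered sites are masked
  gr2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 1, width = 1000), score = 50)
  tp2 <- encodeSignalToTiming(gr2, g)
  expect_identical(validMask(tp2)$chr1, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(replicationTimes(tp2)$chr1[2:3])))
  expect_error(encodeSignalToTiming(mk(c(150, 0, 0)), g), "\\[0, 100\\]")
})

test_that("track binning supports mean, sum and max", {
  g <- genomeGrid(c(chr1 = 2L))
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 751), width = c(750, 500)),
    score = c(4, 8))
  expect_equal(binTrackToGrid(gr, g, "mean")$chr1,
               c((4 * 750 + 8 * 250) / 1000, 8))
  expect_equal(binTrackToGrid(gr, g, "sum")$chr1,
               c(4 * 0.75 + 8 * 0.25, 8 * 0.25))
  expect_equal(binTrackToGrid(gr, g, "max")$chr1, c(8, 8))
})

test_that("sigmoid fit recovers the median replication time", {
  g <- genomeGrid(c(c1 = 1L))
  mids <- (1:16 - 0.5) * 37.5
  mkFrac <- function(y) repliseqFractions(mids, matrix(y, nrow = 1), g)
  # noiseless logistic, t0 = 240, k = 0.05
  y <- 100 / (1 + exp(-0.05 * (mids - 240)))
  r <- fitSigmoidTrep(mkFrac(y), 1)
  expect_equal(r$trep, 240, tolerance = 1e-6)
  expect_identical(r$method, "sigmoid")
  # step 0 -> 100 between bins 7 and 8 brackets t_rep
  ystep <- c(rep(0, 7), rep(100, 9))
  r2 <- fitSigmoidTrep(mkFrac(ystep), 1)
  expect_gt(r2$trep, mids[7])
  expect_lt(r2$trep, mids[8])
  # degenerate rows are masked
  expect_identical(fitSigmoidTrep(mkFrac(rep(0, 16)), 1)$method, "masked")
  expect_identical(fitSigmoidTrep(mkFrac(rep(100, 16)), 1)$method,
                   "masked")
})

test_that("t_rep is equivariant under shifting the bin clock", {
  g <- genomeGrid(c(c1 = 1L))
  mids <- (1:16 - 0.5) * 37.5
  y <- 100 / (1 + exp(-0.04 * (mids - 300)))
  t1 <- fitSigmoidTrep(repliseqFractions(mids, matrix(y, 1), g), 1)$trep
  t2 <- fitSigmoidTrep(repliseqFractions(mids + 55, matrix(y, 1), g),
                       1)$trep
  expect_equal(t2 - t1, 55, tolerance = 1e-6)
})

test_that("noisy 16-bin curves recover t_rep within one bin width", {
  spec <- syntheticSpec(nSites = 100L, originCount = 4L, seed = 19L)
  rates <- genFiringLandscape(spec)
  cfg <- modelConfig(radius = 99L)
  timing <- genObservedTiming(spec, rates, cfg)$timing
  fr <- genFractionHeatmap(timing, nBins = 16L, noiseSdPoints = 5,
                           seed = 21L)
  rec <- trepProfile(fr)
  truth <- replicationTimes(timing)$chrS
  est <- replicationTimes(rec)$chrS
  binWidth <- 600 / 16
  expect_gt(mean(abs(est - truth) <= binWidth, na.rm = TRUE), 0.95)
})

test_that("fraction matrices round trip through TSV", {
  g <- genomeGrid(c(chrS = 4L))
  fr <- repliseqFractions((1:8 - 0.5) * 75,
                          matrix(runif(32, 0, 100), nrow = 4), g)
  p <- tempfile(fileext = ".tsv")
  writeFractionMatrix(fr, p)
  back <- readFractionMatrix(p)
  expect_equal(back@binMidpoints, fr@binMidpoints)
  expect_equal(unname(back@fractions), unname(fr@fractions),
               tolerance = 1e-9)
})
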