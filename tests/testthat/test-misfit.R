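test_that("squared-error profiles match brute-force recomputation", {
  g <- genomeGrid(c(c1 = 50L))
  set.seed(41)
  a <- runif(50, 10, 500)
  b <- runif(50, 10, 500)
  obs <- timingProfile(a, g, "observed")
  pred <- timingProfile(b, g, "predicted")
  expect_equal(siteValues(errorProfile(obs, pred))$c1, (a - b)^2)
  # identical profiles give zero everywhere
  expect_true(all(siteValues(errorProfile(obs, obs))$c1 == 0))
  # a single differing site carries exactly its squared difference
  b2 <- a
  b2[20] <- a[20] + 10
  e <- siteValues(errorProfile(obs, timingProfile(b2, g, "predicted")))$c1
  expect_equal(e[20], 100)
  expect_true(all(e[-20] == 0))
})

test_that("error normalization is a per-chromosome log10 min-max", {
  g <- genomeGrid(c(c1 = 3L))
  mkErr <- function(v) errorProfile(
    timingProfile(sqrt(v) + 10, g, "observed"),
    timingProfile(rep(10, 3), g, "predicted"))
  # crafted triple: log10(e+1) = 0, 1, 2 -> 0, 0.5, 1
  expect_equal(normalizeError(mkErr(c(0, 9, 99)))$c1, c(0, 0.5, 1))
  expect_equal(normalizeError(mkErr(c(5, 5, 5)))$c1, c(0, 0, 0))
  expect_equal(sort(normalizeError(mkErr(c(3, 3, 80)))$c1), c(0, 0, 1))
})

test_that("misfit regions respect threshold, merging and idempotence", {
  n <- 2000L
  g <- genomeGrid(c(c1 = n))
  mkErr <- function(hotRuns) {
    e <- rep(1, n)
    for (r in hotRuns) e[r] <- 10^3.2
    errorProfile(timingProfile(sqrt(e) + 5, g, "observed"),
                 timingProfile(rep(5, n), g, "predicted"))
  }
  # everything below threshold: no calls
  expect_length(detectMisfitRegions(mkErr(list())), 0L)
  # one 50-site run: one region of 50 kb
  r1 <- detectMisfitRegions(mkErr(list(101:150)))
  expect_length(r1, 1L)
  expect_equal(S4Vectors::mcols(r1)$length_kb, 50L)
  expect_equal(S4Vectors::mcols(r1)$start_site, 101L)
  expect_equal(S4Vectors::mcols(r1)$peak_error, 10^3.2)
  # two runs 200 kb apart merge; 400 kb apart stay separate
  rMerge <- detectMisfitRegions(mkErr(list(101:150, 351:400)))
  expect_length(rMerge, 1L)
  expect_equal(S4Vectors::mcols(rMerge)$length_kb, 300L)
  rSplit <- detectMisfitRegions(mkErr(list(101:150, 551:600)))
  expect_length(rSplit, 2L)
  # threshold monotonicity: higher threshold regions lie inside lower ones
  e <- mkErr(list(101:150, 351:400))
  lo <- detectMisfitRegions(e, threshold = 10)
  hi <- detectMisfitRegions(e, threshold = 10^3)
  ov <- GenomicRanges::findOverlaps(hi, lo, type = "within")
  expect_equal(S4Vectors::queryHits(ov), seq_along(hi))
  # deterministic / idempotent
  expect_equal(detectMisfitRegions(e), detectMisfitRegions(e))
})

test_that("misfit fractions count sites class by class", {
  g <- genomeGrid(c(c1 = 100L))
  mask <- list(c1 = rep(FALSE, 100))
  mask$c1[11:20] <- TRUE  # 10 misfit sites
  ann <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(start = (c(11, 31, 16) - 1) * 1000 + 1,
                     end = c(20, 40, 25) * 1000),
    name = c("a", "b", "c"),
    class = c("hit", "miss", "half"))
  fr <- overlapFraction(mask, ann, grid = g)
  expect_equal(fr$misfit_fraction[fr$class == "hit"], 1)
  expect_equal(fr$misfit_fraction[fr$class == "miss"], 0)
  expect_equal(fr$misfit_fraction[fr$class == "half"], 0.5)
  # complement of "hit": 0 misfit sites among the other 90
  expect_equal(fr$complement_fraction[fr$class == "hit"], 0)
  expect_true(all(fr$misfit_fraction >= 0 & fr$misfit_fraction <= 1))
  # class + complement counts recover the genome-wide misfit count
  expect_equal(fr$misfit_sites[fr$class == "hit"] +
                 0.9 * 100 * fr$complement_fraction[fr$class == "hit"],
               10)
})

test_that("track correlations behave across methods", {
  set.seed(43)
  a <- rnorm(40)
  for (m in c("spearman", "pearson", "kendall")) {
    r <- correlateTracks(a, a, method = m)
    expect_equal(r$coefficient, 1)
  }
  # reversing the ranks flips Spearman to -1
  expect_equal(correlateTracks(a, -a, method = "spearman")$coefficient, -1)
  # ten-point crafted sample equals the direct formula
  x <- c(3, 1, 4, 1.5, 5, 9, 2.6, 6, 5.3, 5.8)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 9, 4, 4.5, 9.2)
  r <- correlateTracks(x, y, method = "spearman")
  expect_equal(r$coefficient, cor(rank(x), rank(y)))
  expect_lt(r$p_value, 1)
  # NA sites are dropped pairwise
  x2 <- c(x, NA)
  y2 <- c(y, 5)
  expect_equal(correlateTracks(x2, y2, "pearson")$coefficient,
               cor(x, y))
  expect_error(correlateTracks(c(1, 2), c(3, 4)), ">= 3")
})

test_that("apparent speed is the inverse timing gradient with a floor at v", {
  g <- genomeGrid(c(c1 = 50L))
  tp <- timingProfile((0:49) / 1.4, g, "predicted")
  expect_equal(apparentSpeed(tp)$c1, rep(1.4, 49))
  flat <- timingProfile(rep(7, 50), g, "observed")
  expect_true(all(is.infinite(apparentSpeed(flat)$c1)))
  # model-predicted profiles never go below the fork speed
  set.seed(47)
  rp <- originLandscape(500L, sort(sample.int(500L, 8L)),
                        exp(runif(8, log(1e-3), log(0.1))))
  pred <- expectedTiming(rp, modelConfig(radius = 450L))
  sp <- apparentSpeed(pred)$chrS
  expect_gte(min(sp), 1.4 - 1e-6)
  # injected stalls create sub-v speeds exactly there
  spec <- syntheticSpec(nSites = 500L, originCount = 8L, seed = 47L,
                        stallRegions = data.frame(start = 200L, end = 320L,
                                                  delay = 60))
  obs <- genObservedTiming(spec, genFiringLandscape(spec),
                          modelConfig(radius = 450L))$timing
  spObs <- apparentSpeed(obs)$chrS
  slow <- which(spObs < 1.4 - 1e-6)
  expect_gt(length(slow), 0)
  expect_true(all(slow >= 199 & slow <= 321))
})
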