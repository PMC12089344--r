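test_that("general expectation reduces to the uniform series under uniform rates", {
  set.seed(101)
  for (i in 1:10) {
    f <- exp(runif(1, log(1e-3), log(0.1)))
    v <- runif(1, 0.5, 3)
    cfg <- modelConfig(forkSpeed = v)
    n <- 1001L
    g <- genomeGrid(c(c1 = n))
    tp <- expectedTiming(firingRateProfile(rep(f, n), g), cfg)
    center <- replicationTimes(tp)$c1[(n + 1L) / 2L]
    u <- expectedTimingUniform(f, cfg)
    expect_lt(abs(center - u) / u, 1e-10)
  }
})

test_that("a single origin gives the 1/f + d/v closed form", {
  f <- 0.1
  n <- 301L
  rp <- originLandscape(n, 151L, f)
  tp <- replicationTimes(expectedTiming(rp, modelConfig(radius = 300L)))$chrS
  d <- abs(seq_len(n) - 151L)
  # background 1e-10 perturbs the exact single-origin value negligibly
  expect_equal(tp, 1 / f + d / 1.4, tolerance = 1e-6)
})

test_that("closed form matches the Monte-Carlo mean of the min-formula", {
  set.seed(7)
  n <- 200L
  rp <- originLandscape(n, sort(sample.int(n, 4L)),
                        exp(runif(4, log(0.005), log(0.1))), bg = 1e-4)
  f <- firingRates(rp)$chrS
  pred <- replicationTimes(expectedTiming(rp, modelConfig(radius = 199L)))$chrS
  nrep <- 4000L
  acc <- matrix(0, nrep, n)
  for (r in seq_len(nrep)) acc[r, ] <- minFormulaTiming(rexp(n, f), 1.4)
  se <- apply(acc, 2, sd) / sqrt(nrep)
  expect_true(all(abs(pred - colMeans(acc)) <= 3 * se))
})

test_that("uniform expectation behaves at its limits", {
  # large f/v: only the k = 0 term survives, value -> 1/f
  expect_equal(expectedTimingUniform(50), 1 / 50, tolerance = 1e-10)
  # monotone: faster firing replicates earlier
  set.seed(5)
  f <- sort(exp(runif(8, log(1e-4), log(0.5))))
  u <- expectedTimingUniform(f)
  expect_true(all(diff(u) < 0))
})

test_that("finite-lattice expectation is exact at n = 1 and converges", {
  cfg <- modelConfig()
  expect_identical(expectedTimingUniformFinite(0.01, 1, cfg), 1 / 0.01)
  # independent integral evaluation agrees with the series at large n
  inf <- expectedTimingUniform(0.01, cfg)
  fin <- expectedTimingUniformFinite(0.01, 1e4, cfg)
  expect_lt(abs(fin - inf) / inf, 1e-3)
  expect_lt(abs(fin - inf) / inf, 1e-4)  # 4 significant digits
  # extra origins can only replicate earlier
  ns <- c(1L, 2L, 5L, 17L, 60L, 301L, 1000L)
  vals <- vapply(ns, function(n) expectedTimingUniformFinite(0.02, n, cfg),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("square-root approximation and its inverse are consistent", {
  expect_equal(approxExpectedTiming(pi / (4 * 1.4), 1.4), 1.0)
  # inverse pair, both directions
  expect_equal(approxExpectedTiming(invertTimingUniform(42)), 42)
  expect_equal(invertTimingUniform(100), pi / 5.6e4)
  # inverse-square law: halving T quadruples f
  expect_equal(invertTimingUniform(50) / invertTimingUniform(100), 4)
  # approximation quality across f/v in [1e-5, 1e-1]
  ratios <- 10^seq(-5, -1, length.out = 25)
  v <- 1.4
  for (r in ratios) {
    f <- r * v
    exact <- expectedTimingUniform(f, modelConfig())
    expect_lt(abs(approxExpectedTiming(f, v) - exact) / exact, 0.05)
  }
})

test_that("adjacent predicted times never differ by more than 1/v", {
  set.seed(11)
  for (i in 1:5) {
    n <- 400L
    k <- sample(3:12, 1)
    rp <- originLandscape(n, sort(sample.int(n, k)),
                          exp(runif(k, log(1e-3), log(0.1))))
    cfg <- modelConfig(radius = 350L)
    tp <- replicationTimes(expectedTiming(rp, cfg))$chrS
    expect_true(all(abs(diff(tp)) <= 1 / 1.4 + 1e-9))
  }
})

test_that("raising any one rate weakly lowers every expected time", {
  set.seed(13)
  n <- 80L
  f <- exp(runif(n, log(1e-4), log(0.05)))
  g <- genomeGrid(c(c1 = n))
  cfg <- modelConfig(radius = 79L)
  base <- replicationTimes(expectedTiming(firingRateProfile(f, g), cfg))$c1
  for (j in c(1L, 40L, 80L)) {
    f2 <- f
    f2[j] <- f2[j] * 3
    up <- replicationTimes(expectedTiming(firingRateProfile(f2, g), cfg))$c1
    expect_true(all(up <= base + 1e-12))
    expect_lt(up[j], base[j])
  }
})

test_that("rotation of a circular landscape rotates the timing identically", {
  set.seed(17)
  n <- 120L
  f <- exp(runif(n, log(1e-3), log(0.1)))
  g <- genomeGrid(c(c1 = n))
  cfg <- modelConfig(radius = 59L)
  t0 <- replicationTimes(expectedTiming(firingRateProfile(f, g), cfg,
                                        circular = TRUE))$c1
  shift <- 37L
  f2 <- c(f[(shift + 1):n], f[1:shift])
  t2 <- replicationTimes(expectedTiming(firingRateProfile(f2, g), cfg,
                                        circular = TRUE))$c1
  expect_equal(t2, c(t0[(shift + 1):n], t0[1:shift]), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  g <- genomeGrid(c(c1 = 2L))
  expect_error(expectedTiming(firingRateProfile(c(0.1, 0.1), g)),
               "shorter than 3")
  g3 <- genomeGrid(c(c1 = 3L))
  expect_error(expectedTiming(firingRateProfile(c(0.1, 0, 0.1), g3)),
               "strictly positive")
  expect_error(expectedTimingUniform(0), "must be > 0")
  expect_error(expectedTimingUniformFinite(0.1, 0), "must be >= 1")
  expect_error(invertTimingUniform(-1), "must be > 0")
})
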