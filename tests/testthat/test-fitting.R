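test_that("initialization applies the inverse-square law with clipping", {
  g <- genomeGrid(c(c1 = 5L))
  cfg <- modelConfig()
  r <- firingRates(initializeRates(
    timingProfile(rep(100, 5), g, "observed"), cfg))$c1
  expect_equal(r, rep(pi / (4 * 1.4) / 1e4, 5))
  # strictly increasing T gives strictly decreasing rates
  r2 <- firingRates(initializeRates(
    timingProfile(c(10, 20, 40, 80, 160), g, "observed"), cfg))$c1
  expect_true(all(diff(r2) < 0))
  # very early sites are clipped at the cap
  tCap <- sqrt(pi / (4 * 1.4 * cfg@rateCap))
  r3 <- firingRates(initializeRates(
    timingProfile(rep(tCap / 2, 5), g, "observed"), cfg))$c1
  expect_equal(r3, rep(cfg@rateCap, 5))
  expect_error(initializeRates(timingProfile(rep(1, 5), g, "observed"),
                               modelConfig()) -> x, NA)
  expect_error(initializeRates(
    timingProfile(c(0, 1, 1, 1, 1), g, "observed"), cfg), "must be > 0")
})

test_that("masked sites get interpolated rates and are excluded from MSE", {
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  g <- genomeGrid(c(c1 = 5L), list(c1 = mask))
  T <- c(100, 100, NA, NA, 400)
  rates <- initializeRates(timingProfile(T, g, "observed"), modelConfig())
  f <- firingRates(rates)$c1
  # interpolated timing 100, 200, 300, 400 across the gap
  expect_equal(f[3], invertTimingUniform(200))
  expect_equal(f[4], invertTimingUniform(300))
  expect_true(all(f > 0))
})

test_that("the multiplicative update has the documented arithmetic", {
  n <- 9L
  g <- genomeGrid(c(c1 = n))
  cfg <- modelConfig()
  cur <- firingRateProfile(rep(0.01, n), g)
  obs <- timingProfile(rep(50, n), g, "observed")
  # fixed point: predicted == observed leaves rates unchanged
  same <- timingProfile(rep(50, n), g, "predicted")
  expect_identical(firingRates(updateRates(cur, same, obs, cfg))$c1,
                   rep(0.01, n))
  # predicted = 2x observed at one site, alpha = 2: that rate x4
  pred <- replicationTimes(same)$c1
  pred[5] <- 100
  upd <- firingRates(updateRates(
    cur, timingProfile(pred, g, "predicted"), obs, cfg))$c1
  expect_equal(upd[5], 0.04)
  expect_equal(upd[-5], rep(0.01, n - 1L))
  # zero observed time on a valid site is rejected
  obs0 <- timingProfile(c(rep(50, 8), 0), g, "observed")
  expect_error(updateRates(cur, same, obs0, cfg), "zero observed")
})

test_that("fitting forward-model timing drives the MSE down monotonically", {
  spec <- syntheticSpec(nSites = 2000L, originCount = 10L, seed = 11L)
  rates <- genFiringLandscape(spec)
  cfg <- modelConfig(radius = 500L, maxIterations = 8L)
  obs <- genObservedTiming(spec, rates, cfg)$timing
  fit <- fitFiringRates(obs, cfg)
  tr <- mseTrace(fit)
  expect_length(tr, fit@iterationsRun + 1L)
  expect_true(all(diff(tr) < 0))
  expect_lt(tr[length(tr)], 0.15 * tr[1])
  expect_length(fitWarnings(fit), 0L)
  # deterministic: bit-identical on a rerun
  fit2 <- fitFiringRates(obs, cfg)
  expect_identical(firingRates(fit), firingRates(fit2))
})

test_that("constant observed timing yields a near-uniform fixed point fast", {
  # long enough that chromosome-end effects are a small minority of sites
  g <- genomeGrid(c(c1 = 2000L))
  cfg <- modelConfig(maxIterations = 5L)
  obs <- timingProfile(rep(100, 2000), g, "observed")
  fit <- fitFiringRates(obs, cfg)
  expect_lt(mseTrace(fit)[length(mseTrace(fit))], 1)
  f <- firingRates(fit)$c1
  mid <- f[300:1700]
  expect_lt(diff(range(mid)) / median(mid), 0.05)
})

test_that("rate updates are local: distant edits cannot reach a site", {
  # the series window is hard-capped at R, so K iterations propagate an
  # observed-timing edit at most K*R sites
  spec <- syntheticSpec(nSites = 1200L, originCount = 8L, seed = 23L)
  rates <- genFiringLandscape(spec)
  cfg <- modelConfig(radius = 100L, maxIterations = 3L)
  obs <- genObservedTiming(spec, rates, cfg)$timing
  T2 <- replicationTimes(obs)$chrS
  T2[1000:1020] <- T2[1000:1020] + 30
  obs2 <- timingProfile(T2, profileGrid(obs), "observed")
  f1 <- firingRates(fitFiringRates(obs, cfg))$chrS
  f2 <- firingRates(fitFiringRates(obs2, cfg))$chrS
  reach <- 1000L - (3L + 1L) * 100L - 10L  # edit start - (K+1)*R - slack
  expect_identical(f1[seq_len(reach)], f2[seq_len(reach)])
  expect_false(identical(f1[990:1030], f2[990:1030]))
})

test_that("steep transitions leave residual error at the violating sites", {
  # build observed timing whose slope exceeds the 1/v bound in one place
  n <- 600L
  g <- genomeGrid(c(c1 = n))
  cfg <- modelConfig(radius = 300L, maxIterations = 10L)
  T <- c(seq(20, 60, length.out = 300), seq(60 + 40, 100 + 40,
                                            length.out = 300))
  obs <- timingProfile(T, g, "observed")
  fit <- fitFiringRates(obs, cfg)
  # predicted slope still obeys the fork-speed bound
  pred <- replicationTimes(predictedTiming(fit))$c1
  expect_true(all(abs(diff(pred)) <= 1 / 1.4 + 1e-9))
  # residual error concentrates around the 40-min jump at site 300/301
  e <- siteValues(fitErrors(fit))$c1
  expect_gt(max(e[280:320]), 10 * max(e[c(1:200, 400:600)]))
})

test_that("cap saturation is surfaced as a warning in the result", {
  g <- genomeGrid(c(c1 = 50L))
  obs <- timingProfile(rep(0.01, 50), g, "observed")
  fit <- fitFiringRates(obs, modelConfig(radius = 49L,
                                         maxIterations = 2L))
  expect_match(fitWarnings(fit), "rate cap")
})
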