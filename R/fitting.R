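#' @include core-model.R
NULL

# clip rates into [floor, cap]
.clipRates <- function(f, config) {
  pmin(pmax(f, config@rateFloor), config@rateCap)
}

# fill masked timing by linear interpolation (constant extrapolation at
# ends) so every site carries a usable rate
.interpolateMasked <- function(T, mask) {
  if (all(mask)) return(T)
  valid <- which(mask)
  if (length(valid) == 0L) stop("all sites are masked")
  if (length(valid) == 1L) {
    T[!mask] <- T[valid]
    return(T)
  }
  filled <- approx(x = valid, y = T[valid], xout = seq_along(T),
                   rule = 2)$y
  filled[valid] <- T[valid]
  filled
}

#' Initialize firing rates from observed timing
#'
#' Seeds the fit with the inverse-square law
#' \eqn{f_j(0) = \frac{\pi}{4v} T_j^{-2}} at every valid site, clipped to
#' \code{[rateFloor, rateCap]}. Masked sites receive rates computed from
#' linearly interpolated timing so that neighbours' predictions remain
#' well defined; the interpolation is flagged in the returned profile's
#' \code{interpolated} attribute.
#'
#' @param observed a [TimingProfile-class]; times must be > 0 on valid
#'   sites.
#' @param config a [ModelConfig-class].
#' @return a [FiringRateProfile-class].
#' @examples
#' g <- genomeGrid(c(chrS = 5L))
#' initializeRates(timingProfile(rep(100, 5), g, "observed"))
#' @export
initializeRates <- function(observed, config = modelConfig()) {
  stopifnot(is(observed, "TimingProfile"), is(config, "ModelConfig"))
  g <- observed@grid
  anyInterp <- FALSE
  vals <- lapply(g@chromNames, function(ch) {
    T <- observed@values[[ch]]
    mask <- g@validMask[[ch]]
    if (any(T[mask] <= 0, na.rm = TRUE) || anyNA(T[mask]))
      stop("observed times must be > 0 on valid sites (chromosome ", ch, ")")
    Tfull <- .interpolateMasked(T, mask)
    .clipRates(invertTimingUniform(Tfull, config@forkSpeed), config)
  })
  names(vals) <- g@chromNames
  out <- new("FiringRateProfile", values = vals, grid = g)
  attr(out, "interpolated") <- !all(unlist(g@validMask))
  out
}

#' Multiplicative firing-rate update
#'
#' One step of the iterative correction
#' \deqn{f_j(k+1) = f_j(k)
#'   \left(\frac{\tilde T_j(k)}{T_j}\right)^{\alpha}:}
#' a site whose predicted time \eqn{\tilde T_j} lags the observation is
#' made to fire faster, and vice versa, with \eqn{\alpha} governing the
#' step strength. Results are clipped to \code{[rateFloor, rateCap]}
#' after every update; masked sites keep their current rates.
#'
#' @param current a [FiringRateProfile-class].
#' @param predicted [TimingProfile-class] predicted from \code{current}.
#' @param observed observed [TimingProfile-class] on the same grid.
#' @param config a [ModelConfig-class].
#' @return updated [FiringRateProfile-class].
#' @export
updateRates <- function(current, predicted, observed,
                        config = modelConfig()) {
  .assertSameGrid(current, predicted)
  .assertSameGrid(current, observed)
  g <- current@grid
  vals <- lapply(g@chromNames, function(ch) {
    f <- current@values[[ch]]
    mask <- g@validMask[[ch]]
    Tobs <- observed@values[[ch]]
    Tpred <- predicted@values[[ch]]
    if (any(Tobs[mask] == 0, na.rm = TRUE))
      stop("zero observed time on a valid site (chromosome ", ch, ")")
    upd <- f
    upd[mask] <- f[mask] * (Tpred[mask] / Tobs[mask])^config@alpha
    .clipRates(upd, config)
  })
  names(vals) <- g@chromNames
  new("FiringRateProfile", values = vals, grid = g)
}

.mseByChrom <- function(observed, predicted) {
  g <- observed@grid
  vapply(g@chromNames, function(ch) {
    mask <- g@validMask[[ch]]
    d <- observed@values[[ch]][mask] - predicted@values[[ch]][mask]
    mean(d^2)
  }, numeric(1))
}

.genomeMSE <- function(observed, predicted) {
  g <- observed@grid
  num <- 0
  den <- 0
  for (ch in g@chromNames) {
    mask <- g@validMask[[ch]]
    d <- observed@values[[ch]][mask] - predicted@values[[ch]][mask]
    num <- num + sum(d^2)
    den <- den + sum(mask)
  }
  num / den
}

#' Fit per-site firing rates to observed replication timing
#'
#' Runs the full inference: inverse-square initialization
#' ([initializeRates()]), then \code{maxIterations} rounds of predict
#' ([expectedTiming()]) and multiplicative update ([updateRates()]),
#' tracking the genome and per-chromosome mean squared error (min^2) at
#' every iteration. Entirely deterministic; chromosomes are independent,
#' so processing order does not affect the result. If more than half of
#' the valid sites end up pinned at the rate cap, a divergence warning is
#' recorded in the result (not raised as an error).
#'
#' @param observed a [TimingProfile-class] (minutes, > 0 on valid sites).
#' @param config a [ModelConfig-class]; \code{earlyStopTol > 0} enables an
#'   optional early stop when the relative MSE improvement falls below
#'   that tolerance.
#' @return a [FitResult-class].
#' @examples
#' spec <- syntheticSpec(nSites = 2000L, originCount = 10L, seed = 11L)
#' rates <- genFiringLandscape(spec)
#' cfg <- modelConfig(radius = 500L, maxIterations = 10L)
#' obs <- genObservedTiming(spec, rates, cfg)$timing
#' fit <- fitFiringRates(obs, cfg)
#' mseTrace(fit)
#' @export
fitFiringRates <- function(observed, config = modelConfig()) {
  stopifnot(is(observed, "TimingProfile"), is(config, "ModelConfig"))
  g <- observed@grid
  if (any(vapply(g@validMask, sum, numeric(1)) < 1))
    stop("every chromosome needs at least one valid site")
  rates <- initializeRates(observed, config)
  predicted <- expectedTiming(rates, config)
  trace <- .genomeMSE(observed, predicted)
  byChrom <- matrix(.mseByChrom(observed, predicted), nrow = 1,
                    dimnames = list(NULL, g@chromNames))
  k <- 0L
  while (k < config@maxIterations) {
    rates <- updateRates(rates, predicted, observed, config)
    predicted <- expectedTiming(rates, config)
    mse <- .genomeMSE(observed, predicted)
    trace <- c(trace, mse)
    byChrom <- rbind(byChrom, .mseByChrom(observed, predicted))
    k <- k + 1L
    if (config@earlyStopTol > 0) {
      prev <- trace[length(trace) - 1L]
      if (prev > 0 && (prev - mse) / prev < config@earlyStopTol) break
    }
  }
  warn <- character()
  fAll <- unlist(rates@values, use.names = FALSE)
  mAll <- unlist(g@validMask, use.names = FALSE)
  capped <- mean(fAll[mAll] >= config@rateCap * (1 - 1e-12))
  if (capped > 0.5)
    warn <- c(warn, sprintf(
      "possible divergence: %.0f%% of valid sites at the rate cap",
      100 * capped))
  new("FitResult", rates = rates, predicted = predicted,
      errors = errorProfile(observed, predicted),
      mseTrace = unname(trace), mseByChrom = byChrom,
      iterationsRun = k, warnings = warn)
}
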