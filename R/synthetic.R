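#' @include core-model.R
NULL

#' Construct a SyntheticSpec
#'
#' @param nSites number of 1-kb sites of the synthetic chromosome.
#' @param originCount number of active origins.
#' @param rateRange (min, max) origin firing rate, 1/min; origin rates
#'   are drawn log-uniformly in this interval, spanning the decades seen
#'   in fitted-rate distributions without committing to a parametric
#'   form.
#' @param backgroundRate rate of all non-origin sites (effectively
#'   passive).
#' @param stallRegions data.frame with columns \code{start}, \code{end}
#'   (1-based sites), \code{delay} (minutes); timing delays the
#'   constant-speed model cannot reproduce.
#' @param noiseSd Gaussian timing-noise sd, minutes.
#' @param seed RNG seed; every generator is a pure function of the spec.
#' @return a [SyntheticSpec-class].
#' @examples
#' syntheticSpec(5000L, 20L, seed = 42L)
#' @export
syntheticSpec <- function(nSites, originCount,
                          rateRange = c(0.001, 0.1),
                          backgroundRate = 1e-10,
                          stallRegions = data.frame(start = integer(),
                                                    end = integer(),
                                                    delay = numeric()),
                          noiseSd = 0, seed = 1L) {
  new("SyntheticSpec", nSites = as.integer(nSites),
      originCount = as.integer(originCount),
      rateRange = as.numeric(rateRange),
      backgroundRate = backgroundRate,
      stallRegions = as.data.frame(stallRegions),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Generate a sparse-origin firing-rate landscape
#'
#' Places \code{originCount} origins at sites drawn without replacement
#' on a single synthetic chromosome (\code{chrS}); each origin gets a
#' log-uniform rate in \code{rateRange}, all other sites the background
#' rate. Bit-identical for identical specs.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [FiringRateProfile-class]; origin sites are recorded in the
#'   \code{origin_sites} attribute.
#' @examples
#' genFiringLandscape(syntheticSpec(1000L, 5L, seed = 3L))
#' @export
genFiringLandscape <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  g <- genomeGrid(c(chrS = spec@nSites))
  withr::with_seed(spec@seed, {
    f <- rep(spec@backgroundRate, spec@nSites)
    sites <- integer(0)
    if (spec@originCount > 0L) {
      sites <- sort(sample.int(spec@nSites, spec@originCount))
      lr <- log(spec@rateRange)
      f[sites] <- exp(runif(spec@originCount, lr[1], lr[2]))
    }
    out <- new("FiringRateProfile",
               values = list(chrS = f), grid = g)
    attr(out, "origin_sites") <- sites
    out
  })
}

# per-site delay vector: full delay inside each region, ramped linearly
# over 10 sites at each edge so no synthetic discontinuity appears
.stallDelays <- function(n, stalls) {
  d <- numeric(n)
  for (r in seq_len(nrow(stalls))) {
    s <- stalls$start[r]
    e <- stalls$end[r]
    j <- s:e
    w <- pmin(1, (j - s + 1) / 10, (e - j + 1) / 10)
    d[j] <- pmax(d[j], stalls$delay[r] * w)
  }
  d
}

#' Generate observed timing with optional stalls and noise
#'
#' Forward-computes the model's expected timing from a rate landscape,
#' then perturbs it the way replication stress would: adds
#' \code{delay} minutes inside each stall region (linearly ramped over 10
#' sites at each edge, producing local apparent speeds below the fork
#' speed that the constant-speed model cannot fit) and Gaussian noise of
#' sd \code{noiseSd}. With no stalls and no noise the output is exactly
#' the forward-model prediction. The ground-truth stall intervals are
#' returned so detector recall/precision can be computed exactly.
#'
#' @param spec a [SyntheticSpec-class].
#' @param rates a [FiringRateProfile-class] (typically from
#'   [genFiringLandscape()]).
#' @param config a [ModelConfig-class].
#' @return list with \code{timing} (an observed [TimingProfile-class]),
#'   \code{clean} (the unperturbed predicted profile) and \code{stalls}
#'   (the ground-truth stall data.frame).
#' @export
genObservedTiming <- function(spec, rates, config = modelConfig()) {
  stopifnot(is(spec, "SyntheticSpec"), is(rates, "FiringRateProfile"))
  clean <- expectedTiming(rates, config)
  T <- clean@values[[1L]]
  if (nrow(spec@stallRegions))
    T <- T + .stallDelays(length(T), spec@stallRegions)
  if (spec@noiseSd > 0) {
    T <- withr::with_seed(spec@seed + 1L,
                          pmax(T + rnorm(length(T), 0, spec@noiseSd), 0))
  }
  timing <- new("TimingProfile", values = setNames(list(T), names(clean@values)),
                grid = rates@grid, provenance = "observed")
  list(timing = timing, clean = clean, stalls = spec@stallRegions)
}

#' Generate a synthetic cumulative-fraction heatmap
#'
#' Emulates a high-resolution Repli-seq heatmap: per site, the cumulative
#' percent-replicated curve is a logistic centred at the site's
#' replication time with a transition width set by \code{spreadMinutes},
#' sampled at \code{nBins} bin midpoints spanning \code{sSpan} minutes,
#' plus Gaussian noise truncated to [0, 100]. The generating times (the
#' ground truth that [trepProfile()] should recover) are the input
#' timing.
#'
#' @param timing a [TimingProfile-class].
#' @param nBins number of S-phase bins (>= 4, typically 16).
#' @param spreadMinutes 10-90 percent rise width of the transition.
#' @param noiseSdPoints sd of the added noise, percentage points.
#' @param seed RNG seed.
#' @param sSpan S-phase length covered by the bins, minutes.
#' @return a [RepliseqFractions-class].
#' @export
genFractionHeatmap <- function(timing, nBins = 16L, spreadMinutes = 60,
                               noiseSdPoints = 5, seed = 1L,
                               sSpan = 600) {
  stopifnot(is(timing, "TimingProfile"), nBins >= 4L)
  g <- timing@grid
  T <- unlist(timing@values, use.names = FALSE)
  width <- sSpan / nBins
  mids <- (seq_len(nBins) - 0.5) * width
  k <- 2 * log(9) / spreadMinutes  # 10-90% rise over spreadMinutes
  F <- 100 / (1 + exp(-k * outer(T, mids, function(a, b) b - a)))
  if (noiseSdPoints > 0) {
    F <- withr::with_seed(as.integer(seed), {
      pmin(pmax(F + rnorm(length(F), 0, noiseSdPoints), 0), 100)
    })
  }
  repliseqFractions(mids, F, g)
}

#' Generate a random annotation track
#'
#' Seeded non-overlapping labelled intervals on a grid, for
#' overlap-fraction analyses. Interval lengths are uniform in
#' \code{lengthRange} (kb) and class labels are assigned uniformly from
#' \code{classLabels}.
#'
#' @param nIntervals number of intervals to place.
#' @param lengthRange (min, max) interval length, kb.
#' @param classLabels character vector of class labels.
#' @param seed RNG seed.
#' @param grid a [GenomeGrid-class].
#' @param maxTries rejection-sampling attempts per interval.
#' @return sorted \code{GRanges} with \code{name} and \code{class}
#'   columns (bp coordinates, 1-based closed).
#' @export
genIntervalTrack <- function(nIntervals, lengthRange, classLabels, seed,
                             grid, maxTries = 1000L) {
  stopifnot(nIntervals >= 0L, length(lengthRange) == 2L)
  if (nIntervals == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character()
    S4Vectors::mcols(gr)$class <- character()
    return(gr)
  }
  withr::with_seed(as.integer(seed), {
    placed <- list()
    for (i in seq_len(nIntervals)) {
      for (try in seq_len(maxTries)) {
        ch <- sample(grid@chromNames, 1L)
        n <- grid@sitesPerChrom[[ch]]
        len <- sample(lengthRange[1]:lengthRange[2], 1L)
        if (len > n) next
        s <- sample.int(n - len + 1L, 1L)
        cand <- c(ch, s, s + len - 1L)
        clash <- any(vapply(placed, function(p)
          p[1] == ch && !(as.integer(cand[2]) > as.integer(p[3]) ||
                            as.integer(cand[3]) < as.integer(p[2])),
          logical(1)))
        if (!clash) {
          placed[[length(placed) + 1L]] <- cand
          break
        }
      }
    }
    if (!length(placed)) stop("could not place any interval")
    ch <- vapply(placed, `[[`, character(1), 1L)
    s <- as.integer(vapply(placed, `[[`, character(1), 2L))
    e <- as.integer(vapply(placed, `[[`, character(1), 3L))
    cls <- sample(classLabels, length(placed), replace = TRUE)
    gr <- GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = (s - 1L) * 1000L + 1L,
                                end = e * 1000L),
      name = sprintf("ivl_%d", seq_along(ch)),
      class = cls)
    GenomicRanges::sort(gr)
  })
}
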