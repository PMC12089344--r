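#' @import methods
#' @importFrom stats approx cor.test median nls quantile rexp rnorm runif
#'   sd setNames complete.cases coef predict
#' @importFrom utils read.table write.table packageVersion head tail
#' @useDynLib RepliFit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenomeGrid: the 1-kb site lattice
#'
#' A \code{GenomeGrid} describes the discrete 1-kb lattice on which all
#' profiles live: one run of sites per chromosome, plus a per-site validity
#' mask (\code{FALSE} marks sites with no usable data, e.g. unmappable
#' stretches of a Repli-seq track). Site \code{j} (1-based internally)
#' covers base pairs \code{[(j-1)*1000, j*1000)}, 0-based half-open, so the
#' site index / genomic coordinate conversion is bijective.
#'
#' @slot chromNames character vector of chromosome identifiers.
#' @slot sitesPerChrom named integer vector, number of 1-kb sites per
#'   chromosome (all >= 1).
#' @slot validMask named list of logical vectors, one per chromosome, each
#'   of length \code{sitesPerChrom[chrom]}.
#'
#' @seealso [genomeGrid()], [siteToCoord()], [coordToSite()]
#' @name GenomeGrid-class
#' @rdname GenomeGrid-class
#' @exportClass GenomeGrid
setClass("GenomeGrid",
  slots = c(
    chromNames = "character",
    sitesPerChrom = "integer",
    validMask = "list"
  )
)

setValidity("GenomeGrid", function(object) {
  msg <- character()
  if (length(object@chromNames) == 0L)
    msg <- c(msg, "grid must contain at least one chromosome")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "duplicated chromosome names")
  if (!identical(names(object@sitesPerChrom), object@chromNames))
    msg <- c(msg, "sitesPerChrom must be named by chromNames, in order")
  if (any(object@sitesPerChrom < 1L))
    msg <- c(msg, "every chromosome needs >= 1 site")
  if (!identical(names(object@validMask), object@chromNames))
    msg <- c(msg, "validMask must be named by chromNames, in order")
  ok <- mapply(function(m, n) is.logical(m) && length(m) == n && !anyNA(m),
               object@validMask, object@sitesPerChrom)
  if (!all(ok))
    msg <- c(msg, "each validMask entry must be a logical vector matching the site count")
  if (length(msg)) msg else TRUE
})

#' SiteProfile: per-site values on a GenomeGrid
#'
#' Virtual parent of [FiringRateProfile-class] and [TimingProfile-class]:
#' one numeric value per 1-kb site, stored per chromosome.
#'
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot grid the [GenomeGrid-class] the values live on.
#'
#' @name SiteProfile-class
#' @rdname SiteProfile-class
#' @exportClass SiteProfile
setClass("SiteProfile",
  representation("VIRTUAL",
    values = "list",
    grid = "GenomeGrid"
  )
)

setValidity("SiteProfile", function(object) {
  msg <- character()
  g <- object@grid
  if (!identical(names(object@values), g@chromNames))
    msg <- c(msg, "values must be named by the grid's chromosomes, in order")
  ok <- mapply(function(v, n) is.numeric(v) && length(v) == n,
               object@values, g@sitesPerChrom)
  if (!all(ok))
    msg <- c(msg, "each values entry must be numeric and match the site count")
  if (length(msg)) msg else TRUE
})

#' FiringRateProfile: per-site origin firing rates
#'
#' Per-site origin firing rates \eqn{f_j} in 1/min on a [GenomeGrid-class].
#' Every 1-kb site is a potential replication origin whose firing waiting
#' time is exponential with rate \eqn{f_j}; fitting drives most rates to
#' negligible values, effectively switching those origins off while keeping
#' them strictly positive.
#'
#' @name FiringRateProfile-class
#' @rdname FiringRateProfile-class
#' @exportClass FiringRateProfile
setClass("FiringRateProfile", contains = "SiteProfile")

setValidity("FiringRateProfile", function(object) {
  bad <- vapply(object@values, function(v) any(!is.finite(v) | v < 0),
                logical(1))
  if (any(bad)) "firing rates must be finite and >= 0" else TRUE
})

#' TimingProfile: per-site replication time
#'
#' Replication time \eqn{T_j} in minutes from the start of S phase, per
#' 1-kb site. Masked sites (grid validity mask \code{FALSE}) carry
#' \code{NA}. \code{provenance} records where the profile came from:
#' \code{"observed"} (experimental), \code{"predicted"} (closed-form
#' expectation) or \code{"simulated-mean"} (ensemble average).
#'
#' @slot provenance one of \code{"observed"}, \code{"predicted"},
#'   \code{"simulated-mean"}.
#'
#' @name TimingProfile-class
#' @rdname TimingProfile-class
#' @exportClass TimingProfile
setClass("TimingProfile",
  contains = "SiteProfile",
  slots = c(provenance = "character")
)

setValidity("TimingProfile", function(object) {
  msg <- character()
  if (!(length(object@provenance) == 1L &&
        object@provenance %in% c("observed", "predicted", "simulated-mean")))
    msg <- c(msg, "provenance must be one of observed/predicted/simulated-mean")
  bad <- mapply(function(v, m) any(!is.finite(v[m]) | v[m] < 0),
                object@values, object@grid@validMask)
  if (any(bad))
    msg <- c(msg, "times must be finite and >= 0 on valid sites")
  if (length(msg)) msg else TRUE
})

#' ErrorProfile: per-site squared timing error
#'
#' Squared difference between observed and predicted replication time,
#' \eqn{(T_j - \tilde T_j)^2}, in min^2; \code{NA} where either input is
#' masked.
#'
#' @name ErrorProfile-class
#' @rdname ErrorProfile-class
#' @exportClass ErrorProfile
setClass("ErrorProfile", contains = "SiteProfile")

setValidity("ErrorProfile", function(object) {
  bad <- vapply(object@values,
                function(v) any(is.finite(v) & v < 0), logical(1))
  if (any(bad)) "squared errors must be >= 0" else TRUE
})

#' ModelConfig: global model parameters
#'
#' All tunable parameters of the replication model, with the defaults used
#' throughout: fork speed \eqn{v} = 1.4 kb/min, radius of influence
#' \eqn{R} = 2000 sites (kb), update exponent \eqn{\alpha} = 2, 20 fitting
#' iterations and 500-run simulation ensembles.
#'
#' @slot forkSpeed fork speed \eqn{v}, kb/min (> 0).
#' @slot radius radius of influence \eqn{R} in 1-kb sites (>= 1): the
#'   series over neighbour distance is truncated at this radius.
#' @slot alpha exponent of the multiplicative rate update (> 0).
#' @slot maxIterations number of fitting iterations.
#' @slot rateFloor smallest admissible firing rate, 1/min (> 0).
#' @slot rateCap largest admissible firing rate, 1/min (> rateFloor).
#' @slot seriesTailTol truncate the expectation series once its leading
#'   exponential falls below this value.
#' @slot earlyStopTol optional early stop: end fitting when the relative
#'   MSE improvement drops below this (0 disables).
#' @slot nSimulations ensemble size for stochastic simulation.
#' @slot baseSeed base RNG seed; run \code{i} of an ensemble uses
#'   \code{baseSeed + i - 1}.
#' @slot forkMotionMode \code{"erlang"} (each 1-kb fork step takes an
#'   independent Exp(v) time) or \code{"deterministic"} (each step takes
#'   exactly 1/v min).
#'
#' @name ModelConfig-class
#' @rdname ModelConfig-class
#' @exportClass ModelConfig
setClass("ModelConfig",
  slots = c(
    forkSpeed = "numeric",
    radius = "integer",
    alpha = "numeric",
    maxIterations = "integer",
    rateFloor = "numeric",
    rateCap = "numeric",
    seriesTailTol = "numeric",
    earlyStopTol = "numeric",
    nSimulations = "integer",
    baseSeed = "integer",
    forkMotionMode = "character"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@forkSpeed <= 0) msg <- c(msg, "forkSpeed must be > 0")
  if (object@radius < 1L) msg <- c(msg, "radius must be >= 1")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@maxIterations < 0L) msg <- c(msg, "maxIterations must be >= 0")
  if (object@rateFloor <= 0) msg <- c(msg, "rateFloor must be > 0")
  if (object@rateCap <= object@rateFloor)
    msg <- c(msg, "rateCap must exceed rateFloor")
  if (object@seriesTailTol <= 0 || object@seriesTailTol >= 1)
    msg <- c(msg, "seriesTailTol must be in (0, 1)")
  if (object@earlyStopTol < 0) msg <- c(msg, "earlyStopTol must be >= 0")
  if (object@nSimulations < 1L) msg <- c(msg, "nSimulations must be >= 1")
  if (!(object@forkMotionMode %in% c("erlang", "deterministic")))
    msg <- c(msg, "forkMotionMode must be 'erlang' or 'deterministic'")
  if (length(msg)) msg else TRUE
})

#' FitResult: output of the firing-rate fit
#'
#' @slot rates fitted [FiringRateProfile-class].
#' @slot predicted [TimingProfile-class] predicted from the fitted rates.
#' @slot errors [ErrorProfile-class] of per-site squared errors, min^2.
#' @slot mseTrace numeric, genome mean squared error per iteration; entry 1
#'   is the error of the initialization, so the length is
#'   \code{iterationsRun + 1}.
#' @slot mseByChrom matrix of per-chromosome MSE traces (iterations in
#'   rows, chromosomes in columns).
#' @slot iterationsRun number of update iterations actually performed.
#' @slot warnings character vector of non-fatal diagnostics (e.g. rate cap
#'   saturation).
#'
#' @name FitResult-class
#' @rdname FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  slots = c(
    rates = "FiringRateProfile",
    predicted = "TimingProfile",
    errors = "ErrorProfile",
    mseTrace = "numeric",
    mseByChrom = "matrix",
    iterationsRun = "integer",
    warnings = "character"
  )
)

setValidity("FitResult", function(object) {
  if (length(object@mseTrace) != object@iterationsRun + 1L)
    return("mseTrace must have iterationsRun + 1 entries")
  TRUE
})

#' ReplicationRecord: one stochastic replication run
#'
#' State of the genome after a single simulated S phase: when each site was
#' replicated, by what (its own origin firing, or a passing left/right
#' moving fork), and which origins actually fired.
#'
#' @slot times named list of numeric vectors, replication time per site
#'   (minutes).
#' @slot labels named list of character vectors with values
#'   \code{"origin"}, \code{"left_fork"}, \code{"right_fork"}.
#' @slot firedOrigins data.frame with columns \code{chrom}, \code{site}
#'   (1-based), \code{time} (min): origins that fired before being
#'   passively replicated.
#' @slot forkSpans data.frame with columns \code{chrom}, \code{birth},
#'   \code{death} (min) per fork, used for active-fork counting.
#'
#' @name ReplicationRecord-class
#' @rdname ReplicationRecord-class
#' @exportClass ReplicationRecord
setClass("ReplicationRecord",
  slots = c(
    times = "list",
    labels = "list",
    firedOrigins = "data.frame",
    forkSpans = "data.frame"
  )
)

#' SimulationSummary: ensemble-aggregated replication statistics
#'
#' @slot meanTiming [TimingProfile-class] (provenance
#'   \code{"simulated-mean"}): per-site mean replication time.
#' @slot rfd named list of numeric vectors in [-1, 1]: replication fork
#'   directionality, (number of runs replicating the site with a
#'   right-moving fork minus left-moving) / ensemble size; origin-fired
#'   runs contribute 0.
#' @slot directionFractions named list of 3-column matrices (columns
#'   \code{right}, \code{left}, \code{origin}) of per-site fractions,
#'   summing to 1 across columns.
#' @slot iodSamples numeric, inter-origin distances in kb pooled over runs
#'   and chromosomes.
#' @slot repliconLengths numeric, kb replicated per fired origin (its own
#'   firing site plus everything its two forks copied), pooled over runs.
#' @slot timingSD named list: per-site standard deviation of replication
#'   time across the ensemble (minutes); \code{timingSD / sqrt(n)} is the
#'   Monte-Carlo standard error of \code{meanTiming}.
#' @slot activeForkCounts data.frame with \code{bin_start} (min) and
#'   \code{mean_forks}: mean number of concurrently active forks per
#'   1-minute bin.
#' @slot nSimulations ensemble size.
#'
#' @name SimulationSummary-class
#' @rdname SimulationSummary-class
#' @exportClass SimulationSummary
setClass("SimulationSummary",
  slots = c(
    meanTiming = "TimingProfile",
    timingSD = "list",
    rfd = "list",
    directionFractions = "list",
    iodSamples = "numeric",
    repliconLengths = "numeric",
    activeForkCounts = "data.frame",
    nSimulations = "integer"
  )
)

setValidity("SimulationSummary", function(object) {
  bad <- vapply(object@rfd,
                function(v) any(v < -1 - 1e-12 | v > 1 + 1e-12, na.rm = TRUE),
                logical(1))
  if (any(bad)) return("rfd values must lie in [-1, 1]")
  TRUE
})

#' RepliseqFractions: cumulative S-phase replication fractions
#'
#' Site-by-bin matrix of the cumulative percentage of the cell population
#' that has completed replication of each site, sampled at ordered S-phase
#' bin midpoints (the high-resolution Repli-seq representation; typically
#' 16 bins). Percentages run 0-100 and are non-decreasing along bins up to
#' measurement noise.
#'
#' @slot binMidpoints numeric, ordered bin midpoint times (min).
#' @slot fractions numeric matrix, sites x bins, percent replicated.
#' @slot grid the [GenomeGrid-class] the rows map onto (single
#'   chromosome concatenation order).
#'
#' @name RepliseqFractions-class
#' @rdname RepliseqFractions-class
#' @exportClass RepliseqFractions
setClass("RepliseqFractions",
  slots = c(
    binMidpoints = "numeric",
    fractions = "matrix",
    grid = "GenomeGrid"
  )
)

setValidity("RepliseqFractions", function(object) {
  msg <- character()
  if (is.unsorted(object@binMidpoints, strictly = TRUE))
    msg <- c(msg, "binMidpoints must be strictly increasing")
  if (ncol(object@fractions) != length(object@binMidpoints))
    msg <- c(msg, "fractions must have one column per bin")
  if (nrow(object@fractions) != sum(object@grid@sitesPerChrom))
    msg <- c(msg, "fractions must have one row per grid site")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic-data generators
#'
#' Describes a single-chromosome synthetic replication landscape:
#' \code{originCount} sites receive log-uniform firing rates in
#' \code{rateRange}; all other sites sit at \code{backgroundRate}
#' (effectively passive). Optional \code{stallRegions} inject timing delays
#' the constant-fork-speed model cannot reproduce, emulating fork
#' stalling; \code{noiseSd} adds Gaussian measurement noise to generated
#' timing.
#'
#' @slot nSites number of 1-kb sites.
#' @slot originCount number of active origins.
#' @slot rateRange length-2 numeric, (min, max) origin firing rate, 1/min.
#' @slot backgroundRate firing rate of non-origin sites, 1/min.
#' @slot stallRegions data.frame with columns \code{start}, \code{end}
#'   (1-based site indices) and \code{delay} (minutes added inside the
#'   region, ramped at the edges).
#' @slot noiseSd Gaussian timing noise standard deviation, minutes.
#' @slot seed RNG seed; all generators are pure functions of the spec.
#'
#' @name SyntheticSpec-class
#' @rdname SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  slots = c(
    nSites = "integer",
    originCount = "integer",
    rateRange = "numeric",
    backgroundRate = "numeric",
    stallRegions = "data.frame",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSites < 3L) msg <- c(msg, "nSites must be >= 3")
  if (object@originCount < 0L || object@originCount > object@nSites)
    msg <- c(msg, "originCount must be in [0, nSites]")
  if (length(object@rateRange) != 2L || any(object@rateRange <= 0) ||
      object@rateRange[1] > object@rateRange[2])
    msg <- c(msg, "rateRange must be positive and ordered")
  if (object@backgroundRate <= 0)
    msg <- c(msg, "backgroundRate must be > 0")
  if (nrow(object@stallRegions)) {
    sr <- object@stallRegions
    if (!all(c("start", "end", "delay") %in% names(sr)))
      msg <- c(msg, "stallRegions needs columns start, end, delay")
    else if (any(sr$start > sr$end) || any(sr$delay <= 0) ||
             any(sr$start < 1L) || any(sr$end > object@nSites))
      msg <- c(msg, "stallRegions must lie on the lattice with positive delays")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
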