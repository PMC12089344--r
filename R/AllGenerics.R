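#' @include AllClasses.R
NULL

#' Accessors for grid-based objects
#'
#' \code{siteValues} returns the per-chromosome list of values of a
#' profile; \code{profileGrid} the underlying [GenomeGrid-class];
#' \code{chromNames} and \code{nSites} describe a grid (or the grid behind
#' a profile); \code{validMask} the per-chromosome validity mask.
#'
#' @param x a [GenomeGrid-class] or [SiteProfile-class] derivative.
#' @return \code{siteValues}: named list of numeric vectors;
#'   \code{profileGrid}: a \code{GenomeGrid}; \code{chromNames}: character;
#'   \code{nSites}: named integer; \code{validMask}: named list of logical
#'   vectors.
#' @name grid-accessors
#' @aliases siteValues profileGrid chromNames nSites validMask
#' @examples
#' g <- genomeGrid(c(chr1 = 10L))
#' chromNames(g)
#' nSites(g)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("siteValues", function(x) standardGeneric("siteValues"))
#' @rdname grid-accessors
#' @export
setGeneric("profileGrid", function(x) standardGeneric("profileGrid"))
#' @rdname grid-accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname grid-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname grid-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname grid-accessors
setMethod("siteValues", "SiteProfile", function(x) x@values)
#' @rdname grid-accessors
setMethod("profileGrid", "SiteProfile", function(x) x@grid)
#' @rdname grid-accessors
setMethod("chromNames", "GenomeGrid", function(x) x@chromNames)
#' @rdname grid-accessors
setMethod("chromNames", "SiteProfile", function(x) x@grid@chromNames)
#' @rdname grid-accessors
setMethod("nSites", "GenomeGrid", function(x) x@sitesPerChrom)
#' @rdname grid-accessors
setMethod("nSites", "SiteProfile", function(x) x@grid@sitesPerChrom)
#' @rdname grid-accessors
setMethod("validMask", "GenomeGrid", function(x) x@validMask)
#' @rdname grid-accessors
setMethod("validMask", "SiteProfile", function(x) x@grid@validMask)

#' Firing rates and replication times
#'
#' \code{firingRates} extracts the per-chromosome firing-rate vectors of a
#' [FiringRateProfile-class] (or the fitted rates of a
#' [FitResult-class]); \code{replicationTimes} the per-chromosome time
#' vectors of a [TimingProfile-class]; \code{provenance} the origin of a
#' timing profile.
#'
#' @param x the object.
#' @return named list of numeric vectors (or, for \code{provenance}, a
#'   string).
#' @name profile-accessors
#' @aliases firingRates replicationTimes provenance
NULL

#' @rdname profile-accessors
#' @export
setGeneric("firingRates", function(x) standardGeneric("firingRates"))
#' @rdname profile-accessors
#' @export
setGeneric("replicationTimes", function(x) standardGeneric("replicationTimes"))
#' @rdname profile-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname profile-accessors
setMethod("firingRates", "FiringRateProfile", function(x) x@values)
#' @rdname profile-accessors
setMethod("replicationTimes", "TimingProfile", function(x) x@values)
#' @rdname profile-accessors
setMethod("provenance", "TimingProfile", function(x) x@provenance)

#' Accessors for fit results
#'
#' @param x a [FitResult-class].
#' @return \code{fittedRates}: the [FiringRateProfile-class];
#'   \code{predictedTiming}: the [TimingProfile-class]; \code{fitErrors}:
#'   the [ErrorProfile-class]; \code{mseTrace}: numeric vector of
#'   genome-wide mean squared errors (min^2), one entry per iteration
#'   starting at the initialization; \code{fitWarnings}: character.
#' @name fit-accessors
#' @aliases fittedRates predictedTiming fitErrors mseTrace fitWarnings
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fittedRates", function(x) standardGeneric("fittedRates"))
#' @rdname fit-accessors
#' @export
setGeneric("predictedTiming", function(x) standardGeneric("predictedTiming"))
#' @rdname fit-accessors
#' @export
setGeneric("fitErrors", function(x) standardGeneric("fitErrors"))
#' @rdname fit-accessors
#' @export
setGeneric("mseTrace", function(x) standardGeneric("mseTrace"))
#' @rdname fit-accessors
#' @export
setGeneric("fitWarnings", function(x) standardGeneric("fitWarnings"))

#' @rdname fit-accessors
setMethod("fittedRates", "FitResult", function(x) x@rates)
#' @rdname fit-accessors
setMethod("predictedTiming", "FitResult", function(x) x@predicted)
#' @rdname fit-accessors
setMethod("fitErrors", "FitResult", function(x) x@errors)
#' @rdname fit-accessors
setMethod("mseTrace", "FitResult", function(x) x@mseTrace)
#' @rdname fit-accessors
setMethod("firingRates", "FitResult", function(x) x@rates@values)
#' @rdname fit-accessors
setMethod("fitWarnings", "FitResult", function(x) x@warnings)

#' Accessors for simulation summaries
#'
#' @param x a [SimulationSummary-class].
#' @return \code{meanTiming}: [TimingProfile-class]; \code{rfd}: named list
#'   of per-site fork-directionality vectors in [-1, 1];
#'   \code{directionFractions}: list of sites x 3 matrices (right, left,
#'   origin); \code{iodSamples} and \code{repliconLengths}: numeric, kb;
#'   \code{activeForkCounts}: data.frame of mean active forks per 1-min
#'   bin.
#' @name simulation-accessors
#' @aliases meanTiming rfd directionFractions iodSamples repliconLengths
#'   activeForkCounts
NULL

#' @rdname simulation-accessors
#' @export
setGeneric("meanTiming", function(x) standardGeneric("meanTiming"))
#' @rdname simulation-accessors
#' @export
setGeneric("timingSD", function(x) standardGeneric("timingSD"))
#' @rdname simulation-accessors
#' @export
setGeneric("rfd", function(x) standardGeneric("rfd"))
#' @rdname simulation-accessors
#' @export
setGeneric("directionFractions", function(x) standardGeneric("directionFractions"))
#' @rdname simulation-accessors
#' @export
setGeneric("iodSamples", function(x) standardGeneric("iodSamples"))
#' @rdname simulation-accessors
#' @export
setGeneric("repliconLengths", function(x) standardGeneric("repliconLengths"))
#' @rdname simulation-accessors
#' @export
setGeneric("activeForkCounts", function(x) standardGeneric("activeForkCounts"))

#' @rdname simulation-accessors
setMethod("meanTiming", "SimulationSummary", function(x) x@meanTiming)
#' @rdname simulation-accessors
setMethod("timingSD", "SimulationSummary", function(x) x@timingSD)
#' @rdname simulation-accessors
setMethod("rfd", "SimulationSummary", function(x) x@rfd)
#' @rdname simulation-accessors
setMethod("directionFractions", "SimulationSummary",
          function(x) x@directionFractions)
#' @rdname simulation-accessors
setMethod("iodSamples", "SimulationSummary", function(x) x@iodSamples)
#' @rdname simulation-accessors
setMethod("repliconLengths", "SimulationSummary", function(x) x@repliconLengths)
#' @rdname simulation-accessors
setMethod("activeForkCounts", "SimulationSummary",
          function(x) x@activeForkCounts)

setMethod("show", "GenomeGrid", function(object) {
  cat("GenomeGrid with", length(object@chromNames), "chromosome(s),",
      sum(object@sitesPerChrom), "x 1-kb sites\n")
  n <- head(object@chromNames, 5L)
  for (ch in n) {
    cat(sprintf("  %s: %d sites (%d valid)\n", ch,
                object@sitesPerChrom[[ch]], sum(object@validMask[[ch]])))
  }
  if (length(object@chromNames) > 5L) cat("  ...\n")
})

setMethod("show", "FiringRateProfile", function(object) {
  v <- unlist(object@values, use.names = FALSE)
  cat(sprintf(
    "FiringRateProfile: %d sites on %d chromosome(s); rates [%.3g, %.3g] /min\n",
    length(v), length(object@values), min(v), max(v)))
})

setMethod("show", "TimingProfile", function(object) {
  v <- unlist(object@values, use.names = FALSE)
  v <- v[is.finite(v)]
  cat(sprintf(
    "TimingProfile (%s): %d sites on %d chromosome(s); times [%.4g, %.4g] min\n",
    object@provenance, sum(lengths(object@values)), length(object@values),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ErrorProfile", function(object) {
  v <- unlist(object@values, use.names = FALSE)
  v <- v[is.finite(v)]
  cat(sprintf(
    "ErrorProfile: %d valid sites; squared error [%.4g, %.4g] min^2\n",
    length(v), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig:\n")
  cat(sprintf("  fork speed v       = %g kb/min\n", object@forkSpeed))
  cat(sprintf("  radius R           = %d kb\n", object@radius))
  cat(sprintf("  alpha              = %g\n", object@alpha))
  cat(sprintf("  max iterations     = %d\n", object@maxIterations))
  cat(sprintf("  rate floor/cap     = %g / %g /min\n",
              object@rateFloor, object@rateCap))
  cat(sprintf("  simulations        = %d (%s fork motion), base seed %d\n",
              object@nSimulations, object@forkMotionMode, object@baseSeed))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: %d iteration(s); MSE %.4g -> %.4g min^2\n",
    object@iterationsRun, object@mseTrace[1],
    object@mseTrace[length(object@mseTrace)]))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "SimulationSummary", function(object) {
  cat(sprintf(
    "SimulationSummary: %d run(s), %d chromosome(s), %d IOD sample(s)\n",
    object@nSimulations, length(object@rfd), length(object@iodSamples)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d sites, %d origins, rates [%g, %g] /min, seed %d\n",
    object@nSites, object@originCount, object@rateRange[1],
    object@rateRange[2], object@seed))
  if (nrow(object@stallRegions))
    cat(sprintf("  %d stall region(s), noise sd %g min\n",
                nrow(object@stallRegions), object@noiseSd))
})
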