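#' @include AllClasses.R
NULL

#' Construct a GenomeGrid
#'
#' @param sites named integer vector: number of 1-kb sites per chromosome.
#' @param validMask optional named list of logical vectors (defaults to all
#'   valid).
#' @return a [GenomeGrid-class].
#' @examples
#' genomeGrid(c(chr1 = 500L, chr2 = 300L))
#' @export
genomeGrid <- function(sites, validMask = NULL) {
  if (is.null(names(sites)) || any(!nzchar(names(sites))))
    stop("'sites' must be a named vector of site counts")
  sites <- setNames(as.integer(sites), names(sites))
  if (is.null(validMask))
    validMask <- lapply(sites, function(n) rep(TRUE, n))
  validMask <- validMask[names(sites)]
  new("GenomeGrid", chromNames = names(sites), sitesPerChrom = sites,
      validMask = validMask)
}

#' Construct a ModelConfig
#'
#' Defaults follow the study conditions of the model: fork speed 1.4
#' kb/min, radius of influence 2000 kb, update exponent 2, 20 iterations,
#' 500-simulation ensembles with Erlang (exponential per-step) fork motion.
#'
#' @param forkSpeed fork speed v, kb/min.
#' @param radius radius of influence R, in 1-kb sites.
#' @param alpha exponent of the multiplicative rate update.
#' @param maxIterations fitting iterations.
#' @param rateFloor,rateCap admissible firing-rate interval, 1/min.
#' @param seriesTailTol series truncation tolerance for the timing
#'   expectation.
#' @param earlyStopTol stop fitting early when relative MSE improvement
#'   falls below this; 0 disables.
#' @param nSimulations ensemble size.
#' @param baseSeed base RNG seed for ensembles.
#' @param forkMotionMode \code{"erlang"} or \code{"deterministic"}.
#' @return a [ModelConfig-class].
#' @examples
#' modelConfig()
#' modelConfig(forkSpeed = 2, nSimulations = 100L)
#' @export
modelConfig <- function(forkSpeed = 1.4, radius = 2000L, alpha = 2,
                        maxIterations = 20L, rateFloor = 1e-10,
                        rateCap = 10, seriesTailTol = 1e-12,
                        earlyStopTol = 0, nSimulations = 500L,
                        baseSeed = 1L,
                        forkMotionMode = c("erlang", "deterministic")) {
  forkMotionMode <- match.arg(forkMotionMode)
  new("ModelConfig", forkSpeed = forkSpeed, radius = as.integer(radius),
      alpha = alpha, maxIterations = as.integer(maxIterations),
      rateFloor = rateFloor, rateCap = rateCap,
      seriesTailTol = seriesTailTol, earlyStopTol = earlyStopTol,
      nSimulations = as.integer(nSimulations),
      baseSeed = as.integer(baseSeed), forkMotionMode = forkMotionMode)
}

#' Construct per-site profiles
#'
#' \code{firingRateProfile} and \code{timingProfile} wrap per-chromosome
#' value lists (or a single numeric vector for a one-chromosome grid) into
#' validated profile objects.
#'
#' @param values named list of numeric vectors matching the grid, or a
#'   single numeric vector if the grid has one chromosome.
#' @param grid a [GenomeGrid-class].
#' @param provenance for timing profiles: \code{"observed"},
#'   \code{"predicted"} or \code{"simulated-mean"}.
#' @return a [FiringRateProfile-class] / [TimingProfile-class].
#' @examples
#' g <- genomeGrid(c(chrS = 5L))
#' firingRateProfile(rep(0.01, 5), g)
#' timingProfile(1:5, g, "observed")
#' @name profile-constructors
NULL

.asValueList <- function(values, grid) {
  if (!is.list(values)) {
    if (length(grid@chromNames) != 1L)
      stop("a bare vector is only accepted for single-chromosome grids")
    values <- setNames(list(as.numeric(values)), grid@chromNames)
  }
  lapply(values[grid@chromNames], as.numeric)
}

#' @rdname profile-constructors
#' @export
firingRateProfile <- function(values, grid) {
  new("FiringRateProfile", values = .asValueList(values, grid), grid = grid)
}

#' @rdname profile-constructors
#' @export
timingProfile <- function(values, grid,
                          provenance = c("observed", "predicted",
                                         "simulated-mean")) {
  provenance <- match.arg(provenance)
  new("TimingProfile", values = .asValueList(values, grid), grid = grid,
      provenance = provenance)
}

#' Site index / genomic coordinate conversion
#'
#' Site \code{j} (1-based) covers base pairs \code{[(j-1)*1000, j*1000)},
#' 0-based half-open. \code{siteToCoord} returns the interval start/end of
#' each site; \code{coordToSite} the site containing each 0-based position.
#'
#' @param site integer vector of 1-based site indices.
#' @param pos integer vector of 0-based genomic positions (bp).
#' @return \code{siteToCoord}: data.frame with \code{start}, \code{end}
#'   (bp); \code{coordToSite}: integer site indices.
#' @examples
#' siteToCoord(1:3)
#' coordToSite(c(0, 999, 1000))
#' @name site-coords
NULL

#' @rdname site-coords
#' @export
siteToCoord <- function(site) {
  site <- as.integer(site)
  data.frame(start = (site - 1L) * 1000L, end = site * 1000L)
}

#' @rdname site-coords
#' @export
coordToSite <- function(pos) {
  as.integer(pos %/% 1000L) + 1L
}

# shared-grid check used by binary operations
.assertSameGrid <- function(a, b) {
  ga <- a@grid; gb <- b@grid
  if (!identical(ga@chromNames, gb@chromNames) ||
      !identical(ga@sitesPerChrom, gb@sitesPerChrom))
    stop("profiles do not share a grid")
  invisible(TRUE)
}

#' Convert a per-site profile to GRanges
#'
#' Expands a [SiteProfile-class] to a \code{GRanges} with one range per
#' site (1-kb tiles, 1-based closed as GRanges requires; exported bedGraph
#' uses 0-based half-open) and the value in \code{score}.
#'
#' @param x a [SiteProfile-class] derivative.
#' @param dropInvalid drop masked / non-finite sites (default TRUE).
#' @return a \code{GRanges} with a \code{score} metadata column.
#' @examples
#' g <- genomeGrid(c(chrS = 3L))
#' profileToGRanges(timingProfile(c(1, 2, 3), g, "observed"))
#' @export
profileToGRanges <- function(x, dropInvalid = TRUE) {
  g <- x@grid
  parts <- lapply(g@chromNames, function(ch) {
    v <- x@values[[ch]]
    keep <- if (dropInvalid) g@validMask[[ch]] & is.finite(v)
            else rep(TRUE, length(v))
    j <- which(keep)
    list(chrom = rep(ch, length(j)), site = j, score = v[j])
  })
  GenomicRanges::GRanges(
    seqnames = unlist(lapply(parts, `[[`, "chrom")),
    ranges = IRanges::IRanges(
      start = (unlist(lapply(parts, `[[`, "site")) - 1L) * 1000L + 1L,
      width = 1000L),
    score = unlist(lapply(parts, `[[`, "score")))
}
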