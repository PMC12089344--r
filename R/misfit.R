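#' @include grid.R
NULL

#' Per-site squared timing error
#'
#' The misfit at each site: \eqn{(T_j - \tilde T_j)^2} in min^2, the
#' squared difference between observed and model-predicted replication
#' time. Masked wherever either input is masked.
#'
#' @param observed,predicted [TimingProfile-class] objects on the same
#'   grid.
#' @return an [ErrorProfile-class]; its grid's validity mask is the
#'   intersection of the inputs' masks.
#' @examples
#' g <- genomeGrid(c(chrS = 3L))
#' a <- timingProfile(c(10, 20, 30), g, "observed")
#' b <- timingProfile(c(10, 25, 30), g, "predicted")
#' siteValues(errorProfile(a, b))
#' @export
errorProfile <- function(observed, predicted) {
  .assertSameGrid(observed, predicted)
  go <- observed@grid
  gp <- predicted@grid
  mask <- lapply(go@chromNames,
                 function(ch) go@validMask[[ch]] & gp@validMask[[ch]])
  names(mask) <- go@chromNames
  g <- genomeGrid(go@sitesPerChrom, mask)
  vals <- lapply(g@chromNames, function(ch) {
    e <- (observed@values[[ch]] - predicted@values[[ch]])^2
    e[!mask[[ch]]] <- NA_real_
    e
  })
  names(vals) <- g@chromNames
  new("ErrorProfile", values = vals, grid = g)
}

#' Normalize an error profile for display
#'
#' \code{log10_minmax}: per chromosome, \eqn{\log_{10}(e + 1)} followed by
#' min-max scaling to [0, 1]; a constant chromosome maps to 0.
#'
#' @param error an [ErrorProfile-class].
#' @param scheme normalization scheme (only \code{"log10_minmax"}).
#' @return named list of numeric vectors in [0, 1] (NA on masked sites).
#' @export
normalizeError <- function(error, scheme = c("log10_minmax")) {
  scheme <- match.arg(scheme)
  stopifnot(is(error, "ErrorProfile"))
  lapply(error@values, function(e) {
    x <- log10(e + 1)
    r <- range(x, na.rm = TRUE)
    if (!is.finite(r[1]) || r[1] == r[2]) {
      x[] <- ifelse(is.na(x), NA_real_, 0)
      return(x)
    }
    (x - r[1]) / (r[2] - r[1])
  })
}

#' Detect misfit regions
#'
#' Calls contiguous runs of sites whose squared timing error exceeds
#' \code{threshold}; runs separated by gaps of at most \code{mergeRadius}
#' kb are merged into one region. Defaults follow the genome-wide
#' analysis convention: threshold \eqn{10^{2.8}} min^2, 300-kb merge
#' radius. Deterministic and idempotent; raising the threshold only
#' shrinks regions.
#'
#' @param error an [ErrorProfile-class].
#' @param threshold min^2 error above which a site is a misfit site.
#' @param mergeRadius kb; high-error runs closer than this are merged.
#' @return a \code{GRanges} (1-kb-resolution coordinates, 1-based ranges
#'   internally; use [writeMisfitBed()] for 0-based half-open output) with
#'   metadata columns \code{start_site}, \code{end_site} (inclusive,
#'   1-based), \code{peak_error} (min^2) and \code{length_kb}.
#' @examples
#' g <- genomeGrid(c(chrS = 100L))
#' e <- rep(1, 100); e[40:49] <- 1e4
#' obs <- timingProfile(sqrt(e) + 10, g, "observed")
#' prd <- timingProfile(rep(10, 100), g, "predicted")
#' detectMisfitRegions(errorProfile(obs, prd))
#' @export
detectMisfitRegions <- function(error, threshold = 10^2.8,
                                mergeRadius = 300) {
  stopifnot(is(error, "ErrorProfile"), threshold > 0)
  g <- error@grid
  chrom <- character()
  s <- integer()
  w <- integer()
  peak <- numeric()
  for (ch in g@chromNames) {
    e <- error@values[[ch]]
    hot <- !is.na(e) & e > threshold
    if (!any(hot)) next
    ir <- IRanges::IRanges(hot)  # runs of TRUE
    merged <- IRanges::reduce(ir, min.gapwidth = as.integer(mergeRadius) + 1L)
    si <- IRanges::start(merged)
    wi <- IRanges::end(merged)
    peak <- c(peak, vapply(seq_along(merged), function(i)
      max(e[si[i]:wi[i]], na.rm = TRUE), numeric(1)))
    chrom <- c(chrom, rep(ch, length(merged)))
    s <- c(s, si)
    w <- c(w, wi)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (s - 1L) * 1000L + 1L,
                              end = w * 1000L))
  S4Vectors::mcols(gr)$start_site <- s
  S4Vectors::mcols(gr)$end_site <- w
  S4Vectors::mcols(gr)$peak_error <- peak
  S4Vectors::mcols(gr)$length_kb <- w - s + 1L
  gr
}

#' Per-site misfit mask
#'
#' Sites whose squared error exceeds \code{threshold}. The alternative
#' preset \code{threshold = 1e4} reproduces the stricter cut used for
#' coding/non-coding contrasts.
#'
#' @param error an [ErrorProfile-class].
#' @param threshold min^2.
#' @return named list of logical vectors (NA sites are \code{FALSE}).
#' @export
misfitMask <- function(error, threshold = 10^2.8) {
  stopifnot(is(error, "ErrorProfile"))
  lapply(error@values, function(e) !is.na(e) & e > threshold)
}

# map annotation GRanges onto grid sites of one chromosome
.grToSiteMask <- function(gr, chrom, n) {
  m <- rep(FALSE, n)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (!length(gr)) return(m)
  # GRanges is 1-based closed; site j covers bp (j-1)*1000+1 .. j*1000
  s <- pmax(coordToSite(GenomicRanges::start(gr) - 1L), 1L)
  e <- pmin(coordToSite(GenomicRanges::end(gr) - 1L), n)
  for (i in seq_along(s)) if (s[i] <= e[i]) m[s[i]:e[i]] <- TRUE
  m
}

#' Misfit fraction within annotation classes
#'
#' For each annotation class, the fraction of annotated 1-kb sites that
#' are misfit sites, together with the fraction among all sites outside
#' that class (the enrichment baseline).
#'
#' @param misfit either a named list of logical per-site masks (from
#'   [misfitMask()]) or a \code{GRanges} of regions (from
#'   [detectMisfitRegions()]).
#' @param annotations \code{GRanges} with a \code{class} metadata column
#'   (see [readBedIntervals()]); ranges without one are treated as a
#'   single class \code{"interval"}.
#' @param grid the [GenomeGrid-class] (required when \code{misfit} is a
#'   \code{GRanges}).
#' @return data.frame with one row per class: \code{class},
#'   \code{n_sites}, \code{misfit_sites}, \code{misfit_fraction},
#'   \code{complement_fraction}.
#' @export
overlapFraction <- function(misfit, annotations, grid = NULL) {
  if (is(misfit, "GRanges")) {
    if (is.null(grid)) stop("grid required when misfit is a GRanges")
    mask <- lapply(grid@chromNames, function(ch)
      .grToSiteMask(misfit, ch, grid@sitesPerChrom[[ch]]))
    names(mask) <- grid@chromNames
  } else {
    mask <- misfit
    if (is.null(grid))
      grid <- genomeGrid(setNames(lengths(mask), names(mask)))
  }
  cls <- S4Vectors::mcols(annotations)$class
  if (is.null(cls)) cls <- rep("interval", length(annotations))
  classes <- unique(cls)
  totalMisfit <- sum(unlist(mask, use.names = FALSE))
  totalSites <- sum(grid@sitesPerChrom)
  rows <- lapply(classes, function(cl) {
    ann <- annotations[cls == cl]
    inClass <- 0L
    inClassMisfit <- 0L
    for (ch in grid@chromNames) {
      m <- .grToSiteMask(ann, ch, grid@sitesPerChrom[[ch]])
      inClass <- inClass + sum(m)
      inClassMisfit <- inClassMisfit + sum(m & mask[[ch]])
    }
    outClass <- totalSites - inClass
    outMisfit <- totalMisfit - inClassMisfit
    data.frame(class = cl, n_sites = inClass,
               misfit_sites = inClassMisfit,
               misfit_fraction = if (inClass) inClassMisfit / inClass
                                 else NA_real_,
               complement_fraction = if (outClass) outMisfit / outClass
                                     else NA_real_)
  })
  do.call(rbind, rows)
}

#' Correlate two per-site tracks
#'
#' Rank or linear correlation between two genome tracks with
#' pairwise-complete masking, e.g. fitted firing rates vs. a
#' transcription signal, or fit errors vs. chromatin accessibility.
#'
#' @param a,b numeric vectors or named lists of per-site values (lists are
#'   concatenated in order).
#' @param method \code{"spearman"}, \code{"pearson"} or \code{"kendall"}.
#' @return list with \code{coefficient} and \code{p_value} (two-sided,
#'   unadjusted).
#' @examples
#' correlateTracks(1:10, (1:10)^2, method = "spearman")
#' @export
correlateTracks <- function(a, b,
                            method = c("spearman", "pearson", "kendall")) {
  method <- match.arg(method)
  if (is.list(a)) a <- unlist(a, use.names = FALSE)
  if (is.list(b)) b <- unlist(b, use.names = FALSE)
  if (length(a) != length(b)) stop("tracks must have equal length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("need >= 3 jointly valid sites")
  ct <- suppressWarnings(cor.test(a[ok], b[ok], method = method,
                                  exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value)
}

#' Apparent replication speed between adjacent sites
#'
#' The inverse spatial gradient of a timing profile:
#' \eqn{1\,\mathrm{kb} / |T_{j+1} - T_j|} for each adjacent valid pair,
#' with \code{Inf} where the two times coincide. For model-predicted
#' profiles the minimum finite speed is bounded below by the fork speed
#' (1.4 kb/min at defaults); observed profiles dipping below that bound
#' indicate fork slowing or stalling beyond the model's assumptions.
#'
#' @param timing a [TimingProfile-class].
#' @return named list of numeric vectors of length (sites - 1) per
#'   chromosome, kb/min; NA where either site is masked.
#' @examples
#' g <- genomeGrid(c(chrS = 4L))
#' apparentSpeed(timingProfile(c(0, 1, 2, 3) / 1.4, g, "predicted"))
#' @export
apparentSpeed <- function(timing) {
  stopifnot(is(timing, "TimingProfile"))
  g <- timing@grid
  out <- lapply(g@chromNames, function(ch) {
    T <- timing@values[[ch]]
    if (length(T) < 2L) return(numeric(0))
    m <- g@validMask[[ch]]
    dT <- abs(diff(T))
    sp <- ifelse(dT == 0, Inf, 1 / dT)
    sp[!(m[-length(m)] & m[-1L])] <- NA_real_
    sp
  })
  names(out) <- g@chromNames
  out
}
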