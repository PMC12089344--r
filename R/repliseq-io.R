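#' @include grid.R
NULL

# split a bedGraph/BED file into data lines, remembering original line
# numbers for diagnostics
.readTrackLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a bedGraph track
#'
#' Parses 4-column whitespace-delimited bedGraph text (0-based half-open
#' coordinates), skipping \code{track}/\code{browser}/comment lines.
#' Records are validated (start < end, numeric value) with line-numbered
#' error messages, sorted, and overlapping intervals are normalized by a
#' last-writer-wins rule (later lines override earlier ones) with a
#' warning.
#'
#' @param path file path.
#' @param valueUnits free-text description stored in
#'   \code{metadata(x)$value_units}.
#' @return a sorted, non-overlapping \code{GRanges} (1-based closed, as
#'   GRanges represents intervals) with a numeric \code{score} column.
#' @seealso [writeBedGraph()]
#' @export
readBedGraph <- function(path, valueUnits = "") {
  tl <- .readTrackLines(path)
  if (!length(tl$lines)) stop("no data lines in ", path)
  parts <- strsplit(trimws(tl$lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop("line ", tl$lineno[which(nf < 4L)[1]],
         ": expected 4 columns (chrom start end value)")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("line ", tl$lineno[bad[1]], ": non-integer coordinates")
  bad <- which(is.na(value))
  if (length(bad))
    stop("line ", tl$lineno[bad[1]], ": non-numeric value")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", tl$lineno[bad[1]], ": start must be < end")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    score = value, record = seq_along(chrom))
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(self)) {
    warning("overlapping intervals in ", path,
            ": normalized last-writer-wins")
    dj <- GenomicRanges::disjoin(gr)
    hits <- GenomicRanges::findOverlaps(dj, gr)
    win <- tapply(S4Vectors::subjectHits(hits),
                  S4Vectors::queryHits(hits), max)
    S4Vectors::mcols(dj)$score <-
      S4Vectors::mcols(gr)$score[as.integer(win)]
    gr <- dj
  } else {
    S4Vectors::mcols(gr)$record <- NULL
  }
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$value_units <- valueUnits
  gr
}

#' Write a bedGraph track
#'
#' Emits sorted 4-column bedGraph text with 0-based half-open
#' coordinates. Accepts a \code{GRanges} with a \code{score} column or
#' any [SiteProfile-class] (converted via [profileToGRanges()], masked
#' sites dropped).
#'
#' @param x \code{GRanges} or [SiteProfile-class].
#' @param path output path.
#' @param trackName optional name written as a \code{track} header line.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(x, path, trackName = NULL) {
  if (is(x, "SiteProfile")) x <- profileToGRanges(x)
  x <- GenomicRanges::sort(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trackName))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", trackName), con)
  writeLines(sprintf("%s\t%d\t%d\t%.10g",
                     as.character(GenomicRanges::seqnames(x)),
                     GenomicRanges::start(x) - 1L,
                     GenomicRanges::end(x),
                     S4Vectors::mcols(x)$score), con)
  invisible(path)
}

#' Read BED intervals with class labels
#'
#' Parses BED3+ text into a sorted \code{GRanges}. Interval class labels
#' (e.g. common vs. rare fragile sites, genic vs. intergenic) are
#' attached either from \code{classMap} -- a named character vector of
#' regular expressions matched against the BED name column (names are the
#' class labels) -- or from a 5th/extra column if present; unmatched
#' intervals get class \code{"interval"}.
#'
#' @param path file path.
#' @param classMap optional named character vector of name patterns.
#' @return sorted \code{GRanges} with \code{name} and \code{class}
#'   metadata columns.
#' @export
readBedIntervals <- function(path, classMap = NULL) {
  tl <- .readTrackLines(path)
  if (!length(tl$lines)) stop("no data lines in ", path)
  parts <- strsplit(trimws(tl$lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("line ", tl$lineno[which(nf < 3L)[1]],
         ": expected >= 3 columns (chrom start end)")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", tl$lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", tl$lineno[bad[1]], ": start must be < end")
  name <- vapply(seq_along(parts), function(i)
    if (nf[i] >= 4L) parts[[i]][[4L]] else ".", character(1))
  cls <- vapply(seq_along(parts), function(i)
    if (nf[i] >= 5L) parts[[i]][[5L]] else NA_character_, character(1))
  if (!is.null(classMap)) {
    cls <- rep(NA_character_, length(name))
    for (lbl in names(classMap)) {
      hit <- grepl(classMap[[lbl]], name) & is.na(cls)
      cls[hit] <- lbl
    }
  }
  cls[is.na(cls)] <- "interval"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    name = name, class = cls)
  GenomicRanges::sort(gr)
}

#' Bin a signal track onto the 1-kb lattice
#'
#' Aggregates interval values onto each 1-kb site of a grid.
#' \code{mean} is the coverage-weighted mean (each interval contributes
#' proportionally to the bases it covers within the site); \code{sum} is
#' the per-base value summed over covered bases (value x covered kb);
#' \code{max} the maximum value among overlapping intervals. Sites with
#' no coverage are \code{NA}.
#'
#' @param track \code{GRanges} with a \code{score} column.
#' @param grid a [GenomeGrid-class].
#' @param aggregation \code{"mean"}, \code{"sum"} or \code{"max"}.
#' @return named list of per-site numeric vectors.
#' @export
binTrackToGrid <- function(track, grid,
                           aggregation = c("mean", "sum", "max")) {
  aggregation <- match.arg(aggregation)
  out <- lapply(grid@chromNames, function(ch) {
    n <- grid@sitesPerChrom[[ch]]
    res <- rep(NA_real_, n)
    tr <- track[as.character(GenomicRanges::seqnames(track)) == ch]
    if (!length(tr)) return(res)
    tiles <- IRanges::IRanges(start = (seq_len(n) - 1L) * 1000L + 1L,
                              width = 1000L)
    hits <- IRanges::findOverlaps(tiles, GenomicRanges::ranges(tr))
    if (!length(hits)) return(res)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(tiles[q], GenomicRanges::ranges(tr)[s])
    w <- IRanges::width(ov)
    val <- S4Vectors::mcols(tr)$score[s]
    if (aggregation == "mean") {
      num <- tapply(val * w, q, sum)
      den <- tapply(w, q, sum)
      res[as.integer(names(num))] <- num / den
    } else if (aggregation == "sum") {
      num <- tapply(val * w / 1000, q, sum)
      res[as.integer(names(num))] <- num
    } else {
      num <- tapply(val, q, max)
      res[as.integer(names(num))] <- num
    }
    res
  })
  names(out) <- grid@chromNames
  out
}

#' Convert an ENCODE-style wavelet signal to replication timing
#'
#' ENCODE Repli-seq weighted-average signals are normalized 0-100 with
#' high values replicating early. The signal is binned to the 1-kb grid
#' (coverage-weighted mean) and mapped to minutes by rescaling with a
#' factor of 6, aligning the 0-100 range with an approximately 8-hour
#' (600-min after rescaling) S phase:
#' \deqn{T = (100 - s) \times 6}
#' under the default "high = early" orientation (set
#' \code{highSignalEarly = FALSE} to flip). Sites with no signal coverage
#' are masked in the returned profile's grid.
#'
#' @param track \code{GRanges} with \code{score} in [0, 100].
#' @param grid a [GenomeGrid-class].
#' @param scaleFactor rescaling factor (default 6).
#' @param highSignalEarly orientation flag (default TRUE).
#' @param tolerance slack allowed outside [0, 100] before rejection.
#' @return a [TimingProfile-class] (provenance \code{"observed"}) with
#'   \eqn{0 \le T \le 600} on valid sites.
#' @export
encodeSignalToTiming <- function(track, grid, scaleFactor = 6,
                                 highSignalEarly = TRUE,
                                 tolerance = 1e-6) {
  sc <- S4Vectors::mcols(track)$score
  if (any(sc < -tolerance | sc > 100 + tolerance))
    stop("signal values outside [0, 100]")
  binned <- binTrackToGrid(track, grid, aggregation = "mean")
  mask <- lapply(grid@chromNames, function(ch)
    grid@validMask[[ch]] & !is.na(binned[[ch]]))
  names(mask) <- grid@chromNames
  g2 <- genomeGrid(grid@sitesPerChrom, mask)
  vals <- lapply(g2@chromNames, function(ch) {
    s <- pmin(pmax(binned[[ch]], 0), 100)
    T <- if (highSignalEarly) (100 - s) * scaleFactor else s * scaleFactor
    T[!mask[[ch]]] <- NA_real_
    T
  })
  names(vals) <- g2@chromNames
  new("TimingProfile", values = vals, grid = g2, provenance = "observed")
}

#' Construct a RepliseqFractions object
#'
#' @param binMidpoints ordered S-phase bin midpoint times, minutes.
#' @param fractions sites x bins matrix of cumulative percent replicated.
#' @param grid the [GenomeGrid-class] the rows map onto.
#' @return a [RepliseqFractions-class].
#' @export
repliseqFractions <- function(binMidpoints, fractions, grid) {
  new("RepliseqFractions", binMidpoints = as.numeric(binMidpoints),
      fractions = as.matrix(fractions), grid = grid)
}

# linear interpolation of the 50% crossing of a cumulative curve
.linearTrep <- function(t, y) {
  if (y[1] >= 50) return(t[1])
  idx <- which(y >= 50)
  if (!length(idx)) return(t[length(t)])
  i <- idx[1]
  t[i - 1] + (50 - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Median replication time from cumulative S-phase fractions
#'
#' Fits the logistic \eqn{F(t) = 100 / (1 + e^{-k (t - t_0)})} to one
#' site's cumulative replication-fraction curve by Levenberg-Marquardt
#' least squares and returns \eqn{t_0}, the time at which half the cell
#' population has replicated the site (the median replication time,
#' t_rep). When the fit fails to converge the 50 percent crossing is
#' linearly interpolated instead and flagged. All-zero or all-100 sites
#' (no information about the crossing) return \code{NA}.
#'
#' @param fractions a [RepliseqFractions-class].
#' @param site row index of the site.
#' @return list with \code{trep} (minutes, or NA) and \code{method}
#'   (\code{"sigmoid"}, \code{"interpolation"} or \code{"masked"}).
#' @seealso [trepProfile()] for all sites at once.
#' @export
fitSigmoidTrep <- function(fractions, site) {
  stopifnot(is(fractions, "RepliseqFractions"))
  t <- fractions@binMidpoints
  if (length(t) < 4L) stop("need >= 4 bins")
  y <- as.numeric(fractions@fractions[site, ])
  if (all(y <= 1e-9) || all(y >= 100 - 1e-9))
    return(list(trep = NA_real_, method = "masked"))
  t0 <- .linearTrep(t, y)
  span <- diff(range(t))
  fit <- tryCatch({
    df <- data.frame(t = t, y = y)
    m <- minpack.lm::nlsLM(
      y ~ 100 / (1 + exp(-k * (t - t0))), data = df,
      start = list(k = 8 / span, t0 = t0),
      lower = c(1e-6, t[1] - span), upper = c(1e3, t[length(t)] + span),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(trep = coef(m)[["t0"]], method = "sigmoid")
  }, error = function(e) NULL)
  if (is.null(fit)) list(trep = t0, method = "interpolation") else fit
}

#' Median replication time profile
#'
#' Applies [fitSigmoidTrep()] to every site of a fraction matrix and
#' assembles a [TimingProfile-class]; sites where no t_rep is defined are
#' masked. The fraction of sites that needed the interpolation fallback
#' is recorded in the profile's \code{fallback_fraction} attribute.
#'
#' @param fractions a [RepliseqFractions-class].
#' @return a [TimingProfile-class] with provenance \code{"observed"}.
#' @export
trepProfile <- function(fractions) {
  g <- fractions@grid
  nTot <- sum(g@sitesPerChrom)
  trep <- numeric(nTot)
  meth <- character(nTot)
  for (i in seq_len(nTot)) {
    r <- fitSigmoidTrep(fractions, i)
    trep[i] <- if (is.na(r$trep)) NA_real_ else max(r$trep, 0)
    meth[i] <- r$method
  }
  offsets <- cumsum(c(0L, unname(g@sitesPerChrom)))
  vals <- list()
  mask <- list()
  for (ci in seq_along(g@chromNames)) {
    idx <- (offsets[ci] + 1L):offsets[ci + 1L]
    vals[[g@chromNames[ci]]] <- trep[idx]
    mask[[g@chromNames[ci]]] <- g@validMask[[ci]] & !is.na(trep[idx])
  }
  g2 <- genomeGrid(g@sitesPerChrom, mask)
  out <- new("TimingProfile", values = vals, grid = g2,
             provenance = "observed")
  attr(out, "fallback_fraction") <- mean(meth == "interpolation")
  out
}

#' Read / write a site-by-bin fraction matrix
#'
#' Tab-separated matrix with columns \code{chrom}, \code{site} and one
#' column per S-phase bin, the header carrying the bin midpoints (as
#' \code{bin_<minutes>}).
#'
#' @param fractions a [RepliseqFractions-class].
#' @param path file path.
#' @return \code{writeFractionMatrix}: the path, invisibly;
#'   \code{readFractionMatrix}: a [RepliseqFractions-class].
#' @name fraction-matrix-io
NULL

#' @rdname fraction-matrix-io
#' @export
writeFractionMatrix <- function(fractions, path) {
  g <- fractions@grid
  chrom <- rep(g@chromNames, g@sitesPerChrom)
  site <- unlist(lapply(g@sitesPerChrom, seq_len), use.names = FALSE)
  df <- data.frame(chrom = chrom, site = site, fractions@fractions)
  names(df)[-(1:2)] <- sprintf("bin_%g", fractions@binMidpoints)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fraction-matrix-io
#' @export
readFractionMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  binCols <- grep("^bin_", names(df), value = TRUE)
  if (!length(binCols)) stop("no bin_<minutes> columns in ", path)
  mids <- as.numeric(sub("^bin_", "", binCols))
  counts <- table(factor(df$chrom, levels = unique(df$chrom)))
  g <- genomeGrid(setNames(as.integer(counts), names(counts)))
  repliseqFractions(mids, as.matrix(df[, binCols, drop = FALSE]), g)
}

#' Write misfit regions as BED
#'
#' 0-based half-open BED with the peak error (min^2) in the name column.
#'
#' @param regions \code{GRanges} from [detectMisfitRegions()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMisfitBed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g",
                       as.character(GenomicRanges::seqnames(regions)),
                       GenomicRanges::start(regions) - 1L,
                       GenomicRanges::end(regions),
                       S4Vectors::mcols(regions)$peak_error), con)
  }
  invisible(path)
}

#' Build a grid and timing profile from a timing bedGraph
#'
#' Convenience for command-line style inputs: derives the lattice from
#' the track extents (sites out to the furthest covered coordinate per
#' chromosome), bins values to 1-kb sites and masks uncovered sites.
#'
#' @param track \code{GRanges} with \code{score} holding replication
#'   times in minutes.
#' @return a [TimingProfile-class] (provenance \code{"observed"}).
#' @export
trackToTiming <- function(track) {
  chroms <- unique(as.character(GenomicRanges::seqnames(track)))
  sites <- vapply(chroms, function(ch) {
    e <- max(GenomicRanges::end(track[
      as.character(GenomicRanges::seqnames(track)) == ch]))
    coordToSite(e - 1L)
  }, integer(1))
  g0 <- genomeGrid(setNames(sites, chroms))
  binned <- binTrackToGrid(track, g0, "mean")
  mask <- lapply(binned, function(v) !is.na(v))
  g <- genomeGrid(setNames(sites, chroms), mask)
  vals <- lapply(binned, function(v) v)
  new("TimingProfile", values = vals, grid = g, provenance = "observed")
}

#' Build a firing-rate profile from a rates bedGraph
#'
#' @param track \code{GRanges} with \code{score} holding firing rates in
#'   1/min.
#' @param rateFloor rates for uncovered sites (kept strictly positive).
#' @return a [FiringRateProfile-class].
#' @export
trackToRates <- function(track, rateFloor = 1e-10) {
  chroms <- unique(as.character(GenomicRanges::seqnames(track)))
  sites <- vapply(chroms, function(ch) {
    e <- max(GenomicRanges::end(track[
      as.character(GenomicRanges::seqnames(track)) == ch]))
    coordToSite(e - 1L)
  }, integer(1))
  g <- genomeGrid(setNames(sites, chroms))
  binned <- binTrackToGrid(track, g, "mean")
  vals <- lapply(binned, function(v) {
    v[is.na(v)] <- rateFloor
    pmax(v, rateFloor)
  })
  new("FiringRateProfile", values = vals, grid = g)
}
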