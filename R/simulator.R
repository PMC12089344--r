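#' @include core-model.R
NULL

#' Sample origin firing times
#'
#' Draws one waiting time per site from \eqn{Exp(f_j)}: the time at which
#' site \eqn{j}'s origin would fire if not passively replicated first.
#' Sites at the rate floor receive astronomically large draws and are
#' effectively passive.
#'
#' @param rates a [FiringRateProfile-class].
#' @param seed integer RNG seed; the draw is a pure function of
#'   (rates, seed). The global RNG state is left untouched.
#' @return named list of numeric vectors (minutes), one per chromosome,
#'   drawn chromosome by chromosome in grid order.
#' @examples
#' g <- genomeGrid(c(chrS = 5L))
#' sampleFiringTimes(firingRateProfile(rep(0.1, 5), g), seed = 7)
#' @export
sampleFiringTimes <- function(rates, seed) {
  stopifnot(is(rates, "FiringRateProfile"))
  withr::with_seed(as.integer(seed), {
    lapply(rates@values, function(f) rexp(length(f), rate = f))
  })
}

# single-chromosome lower-envelope sweep; returns exactly
# A[i*] + |i*-j|/v for the winning origin i* of each site
.minFormulaChrom <- function(A, v) {
  n <- length(A)
  if (!any(is.finite(A)))
    stop("no finite firing time on chromosome")
  j <- seq_len(n)
  keyL <- A - (j - 1) / v
  bestL <- cummax(ifelse(keyL <= cummin(keyL), j, 0L))
  TL <- A[bestL] + (j - bestL) / v
  keyR <- rev(A) - (j - 1) / v
  bestR <- cummax(ifelse(keyR <= cummin(keyR), j, 0L))
  TR <- rev(rev(A)[bestR] + (j - bestR) / v)
  pmin(TL, TR)
}

#' Replication timing of one realization: the min-formula oracle
#'
#' Given realized firing times \eqn{A_i}, the replication time of site
#' \eqn{j} under deterministic fork motion is
#' \deqn{T_j = \min_i \{A_i + |i-j|/v\}:}
#' the earliest arrival over all origins, each origin's fork needing
#' \eqn{|i-j|/v} minutes to cover the distance. Computed in O(n) per
#' chromosome by a two-pass lower-envelope sweep (left-to-right, then
#' right-to-left). Fork blocking does not change these times at constant
#' speed, so this is the exact per-realization solution and the analytic
#' oracle for the simulator's deterministic mode.
#'
#' @param firingTimes numeric vector (single chromosome) or named list of
#'   vectors, minutes; \code{Inf} marks origins that never fire. At least
#'   one finite entry per chromosome.
#' @param v fork speed, kb/min.
#' @return same shape as \code{firingTimes}: per-site replication times.
#' @examples
#' minFormulaTiming(c(5, 1, 9), v = 1)  # 2, 1, 2
#' @export
minFormulaTiming <- function(firingTimes, v = 1.4) {
  if (is.list(firingTimes))
    lapply(firingTimes, .minFormulaChrom, v = v)
  else
    .minFormulaChrom(firingTimes, v)
}

#' Simulate one S phase
#'
#' Event-driven stochastic simulation of a single replication round on a
#' firing-rate landscape: origins fire after exponential waiting times,
#' each firing spawns a left- and a right-moving fork, forks replicate
#' site by site and die on meeting replicated DNA. In
#' \code{forkMotionMode = "erlang"} each 1-kb step takes an independent
#' Exp(v) time (a k-site traversal is Erlang(k, v), mean \eqn{k/v}); in
#' \code{"deterministic"} the arrival at distance d is exactly
#' \eqn{A + d/v} and the result equals [minFormulaTiming()] on the same
#' sampled firing times. An origin passively replicated before its
#' sampled firing time never fires; at a floating-point tie the fork
#' wins.
#'
#' @param rates a [FiringRateProfile-class].
#' @param config a [ModelConfig-class] (fork speed and motion mode).
#' @param seed integer seed; firing times are drawn first (as
#'   [sampleFiringTimes()] would with the same seed), then any fork step
#'   times continue the same stream, chromosome by chromosome.
#' @return a [ReplicationRecord-class].
#' @examples
#' g <- genomeGrid(c(chrS = 50L))
#' f <- rep(1e-9, 50); f[25] <- 1
#' rec <- simulateOnce(firingRateProfile(f, g), modelConfig(), seed = 1)
#' table(rec@labels$chrS)
#' @export
simulateOnce <- function(rates, config = modelConfig(), seed = 1L) {
  stopifnot(is(rates, "FiringRateProfile"), is(config, "ModelConfig"))
  g <- rates@grid
  erlang <- config@forkMotionMode == "erlang"
  labs <- c("origin", "left_fork", "right_fork")
  withr::with_seed(as.integer(seed), {
    times <- list()
    labels <- list()
    fired <- list()
    spans <- list()
    for (ch in g@chromNames) {
      f <- rates@values[[ch]]
      A <- rexp(length(f), rate = f)
      res <- cpp_simulate_once(A, config@forkSpeed, erlang)
      times[[ch]] <- res$time
      labels[[ch]] <- labs[res$label + 1L]
      ori <- which(res$label == 0L)
      fired[[ch]] <- data.frame(chrom = rep(ch, length(ori)), site = ori,
                                time = res$time[ori])
      spans[[ch]] <- data.frame(chrom = rep(ch, length(res$fork_birth)),
                                birth = res$fork_birth,
                                death = res$fork_death)
      attr(times[[ch]], "by_origin") <- res$by_origin + 1L  # 0-based in C++
    }
    new("ReplicationRecord", times = times, labels = labels,
        firedOrigins = do.call(rbind, unname(fired)),
        forkSpans = do.call(rbind, unname(spans)))
  })
}

#' Simulate a replication ensemble
#'
#' Runs [simulateOnce()] \code{nSimulations} times (run \code{i} seeded
#' with \code{baseSeed + i - 1}) and aggregates:
#' \itemize{
#'   \item mean replication timing per site;
#'   \item replication fork directionality,
#'     \eqn{RFD_j = (\#right - \#left)/n_{sim}} in [-1, 1], where runs in
#'     which the site fired its own origin contribute 0;
#'   \item per-site fractions of right-fork / left-fork / origin
#'     replication (summing to 1);
#'   \item inter-origin distances: distances in kb between consecutive
#'     fired origins within each chromosome and run;
#'   \item replicon lengths: kb replicated by each fired origin (its own
#'     site plus everything its two forks copied); within a run these sum
#'     to the chromosome length;
#'   \item mean number of concurrently active forks per 1-minute bin.
#' }
#'
#' @param rates a [FiringRateProfile-class].
#' @param config a [ModelConfig-class].
#' @return a [SimulationSummary-class].
#' @examples
#' g <- genomeGrid(c(chrS = 60L))
#' f <- rep(1e-9, 60); f[c(20, 40)] <- 1
#' simulateEnsemble(firingRateProfile(f, g),
#'                  modelConfig(nSimulations = 20L))
#' @export
simulateEnsemble <- function(rates, config = modelConfig()) {
  stopifnot(is(rates, "FiringRateProfile"), is(config, "ModelConfig"))
  g <- rates@grid
  nsim <- config@nSimulations
  sumT <- lapply(g@sitesPerChrom, numeric)
  sumT2 <- lapply(g@sitesPerChrom, numeric)
  nR <- lapply(g@sitesPerChrom, numeric)
  nL <- lapply(g@sitesPerChrom, numeric)
  nO <- lapply(g@sitesPerChrom, numeric)
  iod <- list()
  repl <- list()
  forkBins <- numeric(0)

  for (i in seq_len(nsim)) {
    rec <- simulateOnce(rates, config, seed = config@baseSeed + i - 1L)
    for (ch in g@chromNames) {
      byo <- attr(rec@times[[ch]], "by_origin")
      tt <- as.vector(rec@times[[ch]])
      lb <- rec@labels[[ch]]
      sumT[[ch]] <- sumT[[ch]] + tt
      sumT2[[ch]] <- sumT2[[ch]] + tt^2
      nR[[ch]] <- nR[[ch]] + (lb == "right_fork")
      nL[[ch]] <- nL[[ch]] + (lb == "left_fork")
      nO[[ch]] <- nO[[ch]] + (lb == "origin")
      ori <- which(lb == "origin")
      if (length(ori) > 1L)
        iod[[length(iod) + 1L]] <- diff(ori)
      if (length(ori)) {
        repl[[length(repl) + 1L]] <- as.numeric(tabulate(
          match(byo, ori), nbins = length(ori)))
      }
    }
    fs <- rec@forkSpans
    if (nrow(fs)) {
      hi <- floor(fs$death) + 1L
      need <- max(hi)
      if (need > length(forkBins))
        forkBins <- c(forkBins, numeric(need - length(forkBins)))
      for (r in seq_len(nrow(fs))) {
        b <- (floor(fs$birth[r]) + 1L):hi[r]
        forkBins[b] <- forkBins[b] + 1
      }
    }
  }

  meanT <- lapply(g@chromNames, function(ch) sumT[[ch]] / nsim)
  names(meanT) <- g@chromNames
  sdT <- lapply(g@chromNames, function(ch) {
    if (nsim < 2L) return(rep(NA_real_, length(sumT[[ch]])))
    v <- (sumT2[[ch]] - sumT[[ch]]^2 / nsim) / (nsim - 1L)
    sqrt(pmax(v, 0))
  })
  names(sdT) <- g@chromNames
  rfdL <- lapply(g@chromNames, function(ch) (nR[[ch]] - nL[[ch]]) / nsim)
  names(rfdL) <- g@chromNames
  fr <- lapply(g@chromNames, function(ch) {
    m <- cbind(right = nR[[ch]], left = nL[[ch]], origin = nO[[ch]]) / nsim
    m
  })
  names(fr) <- g@chromNames
  afc <- data.frame(bin_start = seq_along(forkBins) - 1,
                    mean_forks = forkBins / nsim)
  new("SimulationSummary",
      meanTiming = new("TimingProfile", values = meanT, grid = g,
                       provenance = "simulated-mean"),
      timingSD = sdT, rfd = rfdL, directionFractions = fr,
      iodSamples = as.numeric(unlist(iod, use.names = FALSE)),
      repliconLengths = as.numeric(unlist(repl, use.names = FALSE)),
      activeForkCounts = afc, nSimulations = nsim)
}
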