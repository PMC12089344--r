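#' @include grid.R
NULL

#' Expected replication timing from a firing-rate landscape
#'
#' Evaluates the closed-form expectation of replication time at every 1-kb
#' site, given per-site origin firing rates, under exponential firing and
#' constant-speed bidirectional fork progression:
#' \deqn{E[T_j] = \sum_{k=0}^{R}
#'   \frac{e^{-S_k/v} - e^{-(S_k+W_k)/v}}{W_k},}
#' where \eqn{W_k = \sum_{|i|\le k} f_{j+i}} and
#' \eqn{S_k = \sum_{|i|\le k} (k-|i|) f_{j+i}}. The sum runs over neighbour
#' distance \eqn{k} up to the radius of influence \eqn{R}, with early
#' truncation once the leading exponential drops below
#' \code{seriesTailTol}; a vanishing \eqn{W_k} term is replaced by its
#' analytic limit \eqn{e^{-S_k/v}/v}. Windows are clamped at chromosome
#' ends (missing flank treated as rate 0) unless \code{circular}.
#'
#' Adjacent predicted times always differ by at most \eqn{1/v} minutes, so
#' the apparent replication speed of a predicted profile never falls below
#' the fork speed (1.4 kb/min at defaults).
#'
#' @param rates a [FiringRateProfile-class] with strictly positive rates.
#' @param config a [ModelConfig-class].
#' @param circular evaluate on a circular lattice (wraparound indices);
#'   used for toy genomes, not real chromosomes.
#' @return a [TimingProfile-class] with provenance \code{"predicted"}.
#' @examples
#' g <- genomeGrid(c(chrS = 200L))
#' f <- rep(1e-9, 200); f[100] <- 0.1
#' tp <- expectedTiming(firingRateProfile(f, g), modelConfig(radius = 150L))
#' replicationTimes(tp)$chrS[c(90, 100, 110)]
#' @seealso [expectedTimingUniform()] for the uniform-rate special case,
#'   [minFormulaTiming()] for the per-realization oracle.
#' @export
expectedTiming <- function(rates, config = modelConfig(), circular = FALSE) {
  stopifnot(is(rates, "FiringRateProfile"), is(config, "ModelConfig"))
  g <- rates@grid
  if (any(g@sitesPerChrom < 3L))
    stop("chromosomes shorter than 3 sites are not supported")
  vals <- lapply(g@chromNames, function(ch) {
    f <- rates@values[[ch]]
    if (any(f <= 0))
      stop("all firing rates must be strictly positive (chromosome ", ch, ")")
    cpp_expected_timing(f, config@forkSpeed, config@radius,
                        config@seriesTailTol, circular)
  })
  names(vals) <- g@chromNames
  new("TimingProfile", values = vals, grid = g, provenance = "predicted")
}

#' Expected replication time under uniform firing rates
#'
#' The infinite-lattice expectation when every site fires at the same rate
#' \eqn{f}:
#' \deqn{E[T;\infty] = \frac{1}{f} \sum_{k\ge 0}
#'   \frac{e^{-f k^2 / v} - e^{-f (k+1)^2 / v}}{2k+1},}
#' truncated once the leading exponential falls below
#' \code{seriesTailTol}. As \eqn{f/v} grows the value tends to \eqn{1/f}
#' (the site almost always fires before any fork arrives).
#'
#' @param f firing rate, 1/min (> 0). Vectorized.
#' @param config a [ModelConfig-class] (fork speed and series tolerance).
#' @return expected replication time, minutes.
#' @examples
#' expectedTimingUniform(0.01)
#' @export
expectedTimingUniform <- function(f, config = modelConfig()) {
  if (any(f <= 0)) stop("f must be > 0")
  v <- config@forkSpeed
  tol <- config@seriesTailTol
  vapply(f, function(fi) {
    total <- 0
    k <- 0
    repeat {
      lead <- exp(-fi * k^2 / v)
      if (k > 0 && lead < tol) break
      total <- total + (lead - exp(-fi * (k + 1)^2 / v)) / (2 * k + 1)
      k <- k + 1
    }
    total / fi
  }, numeric(1))
}

# offsets of the n-site window centred on the focal site: 0, +1, -1, +2, ...
.finiteWindowDistances <- function(n) {
  off <- integer(n)
  if (n > 1L) {
    alt <- as.integer(ceiling(seq_len(n - 1L) / 2)) *
      rep_len(c(1L, -1L), n - 1L)
    off[-1L] <- alt
  }
  sort(abs(off))
}

#' Expected replication time on a finite uniform lattice
#'
#' Numerically evaluates
#' \deqn{E[T;n] = \int_0^\infty \prod_{i}
#'   \min\{1, e^{-f (t - |i|/v)}\}\, dt}
#' for \eqn{n} potential origins spaced at 1 kb around the focal site
#' (symmetric window; one extra site on the right when \eqn{n} is even,
#' which is where the parity dependence of the exact expression comes
#' from). The integration axis is partitioned at the breakpoints
#' \eqn{|i|/v}, between which the integrand is a single exponential
#' \eqn{a e^{-bt}} and integrates in closed form. The value is
#' non-increasing in \eqn{n} and converges to [expectedTimingUniform()] as
#' \eqn{n \to \infty}; \eqn{n = 1} gives exactly \eqn{1/f}.
#'
#' @param f firing rate, 1/min (> 0).
#' @param n number of potential origins (>= 1).
#' @param config a [ModelConfig-class].
#' @return expected replication time, minutes.
#' @examples
#' expectedTimingUniformFinite(0.01, 1)   # 1/f = 100
#' expectedTimingUniformFinite(0.01, 1e4) # close to the infinite lattice
#' @export
expectedTimingUniformFinite <- function(f, n, config = modelConfig()) {
  if (f <= 0) stop("f must be > 0")
  n <- as.integer(n)
  if (n <= 0L) stop("n must be >= 1")
  v <- config@forkSpeed
  d <- .finiteWindowDistances(n)     # sorted |i|, d[1] = 0
  b <- d / v                         # segment breakpoints
  m <- seq_len(n)                    # active-site count per segment
  D <- cumsum(d)                     # sum of the first m distances
  upper <- c(b[-1L], Inf)
  # segment m: exp(f*D_m/v) / (f*m) * (e^{-f m b_m} - e^{-f m b_{m+1}});
  # exponents combined so they stay <= 0
  lo <- exp(f * D / v - f * m * b)
  hi <- ifelse(is.finite(upper), exp(f * D / v - f * m * upper), 0)
  sum((lo - hi) / (f * m))
}

#' Square-root approximation of the uniform expected timing
#'
#' For uniform rates on an infinite lattice the expected replication time
#' is well approximated by
#' \deqn{E[T;\infty] \approx \tfrac{1}{2}\sqrt{\pi/(f v)},}
#' the inverse of [invertTimingUniform()]. The relative error against the
#' exact series stays below 5 percent for \eqn{f/v} up to 0.1.
#'
#' @param f firing rate, 1/min (> 0). Vectorized.
#' @param v fork speed, kb/min.
#' @return approximate expected replication time, minutes.
#' @examples
#' approxExpectedTiming(pi / (4 * 1.4))  # exactly 1
#' @export
approxExpectedTiming <- function(f, v = 1.4) {
  if (any(f <= 0) || v <= 0) stop("f and v must be > 0")
  0.5 * sqrt(pi / (f * v))
}

#' First-estimate firing rate from a replication time
#'
#' Inverts the square-root approximation: a site replicated at time
#' \eqn{T} under uniform-rate assumptions has firing rate
#' \deqn{f \approx \frac{\pi}{4 v} T^{-2}.}
#' This inverse-square law seeds the iterative fit
#' ([initializeRates()]).
#'
#' @param T replication time, minutes (> 0). Vectorized.
#' @param v fork speed, kb/min.
#' @return firing rate, 1/min.
#' @examples
#' invertTimingUniform(100)            # ~5.61e-5 per min
#' approxExpectedTiming(invertTimingUniform(42))  # returns 42
#' @export
invertTimingUniform <- function(T, v = 1.4) {
  if (any(T <= 0)) stop("T must be > 0")
  pi / (4 * v) * T^-2
}
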