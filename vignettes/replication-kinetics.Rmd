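---
title: "Replication kinetics in RepliFit: model, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication kinetics in RepliFit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepliFit)
```

## The model and its assumptions

RepliFit treats each 1-kb site of a genome as a potential replication
origin with an intrinsic firing rate $f_j$ (min$^{-1}$). Three
assumptions define the kinetics:

1. **Exponential firing.** The waiting time for origin $j$ to fire is
   $A_j \sim \mathrm{Exp}(f_j)$, independent across origins and of fork
   movement. The rate absorbs licensing, activation and everything
   upstream of them; no molecular detail is modelled.
2. **Constant fork speed.** A firing origin launches a left- and a
   right-moving fork that each replicate $v$ kb per minute (default
   1.4). Constancy is the load-bearing assumption: if forks could slow
   locally, any timing profile could be fit and the model would lose
   its diagnostic power. Leading/lagging strand asymmetry and Okazaki
   fragments are deliberately out of scope.
3. **Passive replication retires origins.** A site reached by a fork
   before its own firing time is replicated passively and never fires.

For one realization, $T_j = \min_i \{A_i + |i-j|/v\}$. Averaging over
the $A_i$ yields the closed form implemented in `expectedTiming()`:

$$E[T_j] \;=\; \sum_{k=0}^{R}
  \frac{e^{-S_k/v} - e^{-(S_k+W_k)/v}}{W_k},
\qquad
W_k = \!\!\sum_{|i|\le k}\!\! f_{j+i},\quad
S_k = \!\!\sum_{|i|\le k}\!\! (k-|i|)\, f_{j+i}.$$

With uniform rates this reduces to the one-dimensional series of
`expectedTimingUniform()`, approximated by
$E[T] \approx \tfrac12\sqrt{\pi/(fv)}$ (`approxExpectedTiming()`), whose
inverse $f = \frac{\pi}{4v}T^{-2}$ (`invertTimingUniform()`) is accurate
enough to seed the fit. `expectedTimingUniformFinite()` evaluates the
finite-lattice integral
$\int_0^\infty \prod_i \min\{1, e^{-f(t - |i|/v)}\}\,dt$ by partitioning
the axis at the breakpoints $|i|/v$, where each segment is a single
exponential with a closed-form integral; the $n$ potential origins are
laid out as the window centred on the focal site (one extra site on the
right for even $n$, which is where the parity dependence of the exact
expression originates).

A consequence used throughout: adjacent expected times can differ by at
most $1/v$ minutes, so the *apparent replication speed*
$1\,\mathrm{kb}/|T_{j+1}-T_j|$ of any model-predicted profile is bounded
below by $v$. Observed profiles violating the bound cannot be fit, by
design — that failure is the signal `detectMisfitRegions()` harvests.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `forkSpeed` (v) | 1.4 | kb/min | fork progression speed; also the Erlang step rate in simulation |
| `radius` (R) | 2000 | kb (sites) | truncation radius of the neighbour sum; beyond it an origin's influence is dropped |
| `alpha` | 2 | — | exponent of the multiplicative rate update; balances convergence speed against stability |
| `maxIterations` | 20 | — | fitting rounds after initialization |
| `rateFloor` / `rateCap` | 1e-10 / 10 | min⁻¹ | keep every rate strictly positive (every site stays a *potential* origin) and bound the multiplicative update |
| `seriesTailTol` | 1e-12 | — | stop the $k$-sum once $e^{-S_k/v}$ falls below this |
| `nSimulations` | 500 | — | ensemble size for stochastic summaries |
| `forkMotionMode` | `"erlang"` | — | `erlang`: each 1-kb fork step takes Exp(v) time; `deterministic`: exactly $1/v$ |

Units are fixed globally: positions in 1-kb sites, times in minutes,
speeds in kb/min, rates in min$^{-1}$.

## Numerical choices

- **Degenerate series term.** When $W_k$ underflows, the term
  $[e^{-S_k/v} - e^{-(S_k+W_k)/v}]/W_k$ is replaced by its analytic
  limit $e^{-S_k/v}/v$ ($1/v$ when no origin lies within range $k$),
  making the formula exact instead of leaning on the rate floor to
  avoid 0/0. Each term is computed as
  $e^{-S_k/v}\,(-\mathrm{expm1}(-W_k/v))/W_k$ for stability.
- **Recurrences and early stopping.** $W_{k+1} = W_k + f_{j-k-1} +
  f_{j+k+1}$ and $S_{k+1} = S_k + W_k$ give $O(R)$ worst-case work per
  site; since every remaining term is bounded by $e^{-S_k/v}/v$ and
  $S_k$ is non-decreasing, the sum stops once that exponential drops
  below `seriesTailTol`, which in practice is far before $R$ wherever
  rates are appreciable.
- **Chromosome ends.** The window is clamped: out-of-range neighbours
  contribute rate 0. Wrapping around real chromosome ends would be
  biologically wrong; end effects decay within the effective series
  range. A `circular = TRUE` option exists for toy lattices (and powers
  the translation-invariance property test).
- **Clipping.** Rates are clipped into `[rateFloor, rateCap]` after the
  initialization and after *every* multiplicative update, keeping the
  series numerically tame throughout rather than only at the end.
- **Event ties.** In simulation, a floating-point tie between a fork
  arrival and a site's own firing is resolved for the fork: the origin
  is passively replicated, matching the retirement semantics.
- **Min-formula sweep.** `minFormulaTiming()` computes
  $\min_i\{A_i+|i-j|/v\}$ in $O(n)$ with two lower-envelope passes that
  track the winning origin index and evaluate the same floating-point
  expression a deterministic-mode simulation produces, so the two agree
  exactly rather than to rounding.

## Fitting behaviour

`fitFiringRates()` initializes with the inverse-square law, then
alternates closed-form prediction and the update
$f_j \leftarrow f_j (\tilde T_j / T_j)^\alpha$. The map from any one
rate to its predicted time is continuous and monotone, so iterations
behave like a damped fixed-point scheme; the per-iteration MSE trace is
recorded in the result and is strictly decreasing on forward-model
inputs in the test suite. Convergence is geometric and its speed is set
by the *relative* timing misfit: origin peaks and steep flanks correct
within a few iterations, while residual rates in deep inter-origin
valleys (where $\tilde T_j/T_j$ is close to 1) decay slowly. On
noise-free forward-model landscapes of 10 Mb with 50 origins the
20-iteration defaults reach roughly 1–2% of the initialization MSE; the
fixed point itself is exact, so additional iterations keep reducing the
error. Sites with more than half the genome pinned at `rateCap` flag a
divergence warning in the result instead of raising an error.

**Masked sites.** Unmappable stretches keep placeholder rates obtained
from linearly interpolated timing, so neighbouring predictions remain
well defined, but they are excluded from the MSE and from the update;
the interpolation is flagged on the returned profile. A hole in the
rate field would otherwise distort every prediction within $R$ of it.

## What the simulator adds

The event-driven simulator (`simulateOnce()`, `simulateEnsemble()`) is
an independent realization-level implementation: origins fire, forks
step site by site (Erlang traversal times, mean $d/v$), merge on
contact and die at ends. It confirms the closed form (ensemble mean
within Monte-Carlo error of `expectedTiming()` in both fork-motion
modes) and yields quantities the expectation cannot: RFD, IODs,
replicon lengths and active-fork counts. Two conventions are worth
stating: RFD counts a run as 0 at a site replicated by its own origin
firing (neither direction), and replicon lengths attribute every site
to the origin whose fork replicated it, so they partition the
chromosome in every run.

## Repli-seq input conventions

ENCODE-style wavelet signals (0–100) are converted with
$T = (100 - s)\times 6$: the ×6 rescaling aligns the signal range with
an approximately 8-hour (600-min) S phase, and "high signal = early" is
adopted as the standard orientation for weighted-average Repli-seq
signals — the direction is exposed as a flag (`highSignalEarly`) since
conventions vary. No further renormalization is applied, and
low-mappability regions are retained; masking is driven purely by
absent data. Cumulative fraction matrices (typically 16 S-phase bins)
are reduced to the median replication time $t_{rep}$ by a
Levenberg–Marquardt logistic fit per site, falling back to linear
interpolation of the 50% crossing when the fit does not converge (the
fallback fraction is recorded).

## The synthetic generator — and what passing tests do not show

`genFiringLandscape()` et al. emulate exactly the statistical structure
the model assumes: sparse origins with log-uniform rates on a passive
background, constant-speed forward-model timing, optional stall delays
(ramped over 10 sites so no unmeasurable discontinuity appears) and
Gaussian noise. Generators are pure functions of their spec and seed.
Test scales are chosen to keep the default suite fast while preserving
the regimes of interest: 10-Mb / 50-origin genomes for fitting and
misfit detection, 500-site landscapes with $10^4$ Monte-Carlo
replicates or 500-run ensembles for oracle agreement, 1000 sites for
$t_{rep}$ recovery.

Real Repli-seq data differ in ways the generator deliberately does not
imitate: cell-line-specific rate bimodality, spatially correlated noise
and mappability artefacts, S-phase substructure, and origin clustering.
Passing tests therefore demonstrate correctness of the computations and
recoverability under the model's own assumptions — not that any
particular genome satisfies those assumptions.

## Known limitations

- Constant $v$ genome-wide: real fork-speed variation is reported as
  misfit, by construction, rather than modelled.
- The truncation radius bounds origin influence at $R$ kb; in extremely
  origin-poor regions (everything near the rate floor) predicted times
  saturate around $R/v$ plus series tail rather than the true
  (astronomical) expectation.
- Misfit thresholds ($10^{2.8}$ min$^2$, 300-kb merging; $10^4$ min$^2$
  as a stricter preset) are conventions, exposed as parameters.
- Correlation p-values are reported unadjusted; apply multiple-testing
  control downstream when scanning many tracks.
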