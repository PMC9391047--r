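---
title: "Probing time-series causal discovery: models, tests, and failure modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing time-series causal discovery: models, tests, and failure modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalts)
```

## What this package is for

Observational time series invite causal questions that manipulative
experiments cannot always answer: does species 1 drive species 2, or do both
merely follow the seasons? Three families of statistical tools are routinely
pressed into this service — correlation with surrogate-data significance
testing, Granger causality, and state-space-reconstruction (SSR) methods such
as convergent cross mapping (CCM) — and each carries assumptions that are
easy to violate without noticing. `causalts` implements all three families
alongside a suite of toy dynamical systems engineered to expose their known
failure modes, plus benchmark drivers that measure false-positive rates and
tally inference outcomes over noise grids. The goal is diagnostic: to let a
user see, on systems with known ground truth, when each method can be trusted.

## Dependence testing with surrogate data

A single pair of autocorrelated series is effectively one trial, so naive
correlation p-values are meaningless. `dependence_test()` computes the
Pearson correlation $r$ between $X$ and $Y$, then rebuilds the null by
holding $X$ fixed and generating surrogates of $Y$ alone. The p-value is the
add-one counting rule
$$p = \frac{1 + \#\{\,|r_{\mathrm{surr}}| \ge |r_{\mathrm{obs}}|\,\}}{1 + n_{\mathrm{surr}}},$$
two-sided because "at least as strong" is read as magnitude; ties count
toward the numerator, and $p$ can never be exactly 0. With 19 surrogates and
an observation beating all of them, $p = 1/20 = 0.05$ — the smallest level
resolvable at that ensemble size; the default is 99 surrogates.

Three null models are provided. *Permutation* assumes exchangeability, which
autocorrelation violates — the package's false-positive-rate experiments
show rejection rates of 30% and more on independent autocorrelated series.
*Phase randomization* preserves the discrete-Fourier amplitude spectrum
exactly and draws new phases with conjugate symmetry (DC and, for even
lengths, the Nyquist bin are left unrandomized so the output is real-valued);
it is appropriate for linear, Gaussian, stationary processes and holds its
level on the stationary equilibrium island model, but inflates on
nonstationary random walks. *Time shift* circularly rotates the series.
When many independent trials exist, `cross_trial_test()` avoids surrogate
modelling entirely: the mean within-trial correlation is compared with
correlations under random derangements of trial labels, an exact test under
label exchangeability.

## Granger causality

`linear_granger_test()` fits nested one-step-ahead autoregressions by OLS:
the full model regresses $Y_{t+1}$ on lags $1..n$ of $Y$, $X$, and any
conditioning variables; the restricted model zeroes all of $X$'s
coefficients; the comparison is the standard F-test. Two conventions are
deliberate. First, only strictly historical lags enter by default —
contemporaneous terms of the predictors can be admitted with
`include_contemporaneous = TRUE`, but prediction "from the past" is the
cleaner reading and the default is documented prominently. Second, both
directions are tested without multiplicity correction, matching the
per-direction reporting convention of the field.

The test *declines* data (`rejected_data = TRUE`) rather than answering when
the regression cannot support an answer: rank-deficient designs (the
deterministic copy system, where $X(t) = X(t-2)$ exactly, makes lagged
columns collinear) or full-model residual variance below $10^{-12}$ times
the target variance (effectively deterministic dynamics). A declined test is
reported as such and never as evidence for or against causality.

`stationarity_check()` screens the covariance-stationarity assumption with
an augmented Dickey–Fuller-style regression (constant, no trend, lag order
$\lfloor (T-1)^{1/3} \rfloor$, asymptotic 5% critical value $-2.86$) plus a
split-half variance-ratio F-test; either indicator fails the series.
Degenerate regressions (constant input) return `"inconclusive"`.

For Granger causality beyond linearity, `transfer_entropy_binned()` gives the
plug-in estimate of $I(Y_{t+1}; X_{\mathrm{past}} \mid Y_{\mathrm{past}})$
in bits from marginal equal-width binned counts, with $0\log 0 := 0$. The
estimator is biased upward at finite sample size, roughly in proportion to
the number of free cells over the sample size; tests verify it against
exact enumeration on small discrete systems (a fair-coin copy system gives
exactly 1 bit; a three-state Markov toy is matched within 0.02 bits at
$T = 10^5$). Significance (`te_test()`) uses circular time-shift surrogates
of the source only (minimum shift 10 samples), preserving both marginals and
the target's own dynamics. This tests an independence-style null, which is
not identical to the sharp Granger-non-causality null; more refined
surrogate schemes exist but are out of scope, and the limitation is worth
keeping in mind when interpreting rejections.

## State-space reconstruction and CCM

`delay_embed()` builds delay vectors
$[x(t), x(t-\tau), \ldots, x(t-(E-1)\tau)]$. Cross mapping predicts the
*causer* from the delay embedding of the *causee*: the causee's delay
vectors can hold a record of past influence from the causer, so a readable
("continuous") map from causee embedding to causer is taken as evidence that
the causer drives the causee. For each prediction time the $E+1$ nearest
library vectors (Euclidean distance) are combined with weights
$w_i = \exp(-d_i / d_1)$, normalized; cross-map skill $\rho$ is the Pearson
correlation between actual and predicted causer values.

Numerical choices, all configurable:

* **Defaults** $E = 3$, $\tau = 1$, $E + 1$ neighbours. SSR behaviour is
  known to depend on the delay-vector selection; these are the conventional
  starting values, not magic numbers.
* **Exact matches** ($d_1 = 0$) take all the weight, split equally among
  zero-distance neighbours — the limit of the exponential form.
* **Temporal exclusion radius** $\tau E$: library vectors closer than this
  to the query are excluded so skill is not manufactured from trivial
  self-matching. Radius 0 disables all exclusion, which makes the self-map
  sanity check ($\rho = 1$ when a variable cross-maps itself) pass exactly.
* **Library sampling**: contiguous random segments for the convergence
  profile (respecting serial structure), sampling with replacement for the
  bootstrap variant.
* **Prediction-lag ties** break toward the smallest $|$lag$|$, so a perfect
  self-map peaks at lag 0 rather than at an arbitrary tied lag.

Four criteria gate a causal verdict, each optional because applied practice
typically uses a subset: (1) $\rho > 0$; (2) $\rho$ exceeds the skills
obtained with phase-randomized surrogates of the causer, one-sided counting
p-value; (3) skill increases with library size ("convergence"), tested
either by a paired bootstrap at the smallest and largest sizes (main
variant: at least 95% of resampled differences positive) or by a one-sided
Kendall trend test on median skill versus size (alternative variant); and
(4) the prediction-lag test: peak skill at a strictly negative lag. The
verdict is the conjunction of the criteria run. Criterion 4 is excluded by
default: for periodic dynamics skill oscillates as a function of lag and
the test is hard to interpret. The convergence-profile skills are evaluated
on a common random subset of up to 100 prediction times so that library
sizes are compared on the same footing at reasonable cost.

## The toy systems and what they emulate

All simulators are seeded and bit-reproducible; every noise source draws
from its own named substream, so toggling one (say, measurement noise) never
shifts another's draws. Process noise enters recursions and propagates;
measurement noise is added to recorded output only, and the latent
trajectory is retained so tests can verify the separation. The coefficients
of the multivariable systems live in one versioned YAML file
(`system_coefficients()`).

* **Island models** (`simulate_island()`): a random walk of IID standard
  normal increments (nonstationary null), and an immigration–death process
  (immigration 10/step, per-capita death 0.1/step, 1000-step burn-in,
  recorded length 100) whose stationary mean $m/d = 100$ provides a
  closed-form oracle. These are the nulls for the false-positive-rate
  experiments; the recorded length of 100 points is this package's choice of
  a realistic ecological series length.
* **Granger pathologies** (`simulate_granger_pathology()`): the
  deterministic mutual copy system (no-noise false negative); a latent IID
  common cause hitting $Y$ at lag 1 and $Z$ at lag 2 (false positive
  $Y \to Z$); and a linear stochastic chain with unit-variance process
  noise. With the chain's self-couplings zeroed the driver is memoryless,
  which is the regime where sampling every second step erases the
  lag-1 causal signal entirely — with self-memory the signal survives
  composition of steps, so the memoryless variant is the faithful
  realization of the subsampling pathology.
* **Five-variable linear network** (`simulate_linear_network()`): $X, Y, W,
  V$ are exact linear sinusoid oscillators (periods 10, 30, 14, 22, random
  phases), $Z$ a damped linear response to $X$ and $Y$ only; $Z$'s
  fundamental period (30) is three times $X$'s. Shading $Z$'s delay space by
  $Y$ is smooth; by $W$ it is bumpy (`delay_map_shading()` exports the
  table), and cross-map skill quantifies the same contrast.
* **Two-species community** (`simulate_two_species()`): ground truth
  $S_1 \to S_2$ only, with unobserved sinusoidal drivers (periods 23 and 11,
  amplitude 4, random phases per trial) togglable per species,
  linear-with-floor dynamics (abundances clipped at 0), and independently
  tunable process and measurement noise. The functional form is this
  package's own design, built to satisfy the qualitative constraints the
  literature states for such benchmarks: with both drivers the species are
  not synchronized and the true direction is recoverable by CCM in the
  noise-free limit; with only $S_1$'s driver the pair synchronizes and CCM
  degrades; the deterministic limit is declined by the Granger F-test. The
  default recorded length of 400 points covers the joint driver recurrence
  (lcm of the periods, 253 steps), which is what gives a delay embedding
  genuine recurrences to exploit — at 200 points the embedding has no
  revisits and cross mapping is starved of neighbours.
* **SSR pathologies** (`simulate_ssr_pathology()`): a strictly monotone
  "wavy" trend against one arm of a parabola (nonreverting continuous
  dynamics — both delay spaces map continuously to time, hence spuriously
  to each other); a chaotic logistic driver strongly coupled into a
  response (synchrony: bidirectional verdicts despite one-way causation);
  two causally unrelated sinusoids with periods in an exact 5:1 ratio
  ($15\pi$ and $3\pi$ samples — deliberately incommensurate with the unit
  sampling grid, because integer periods create exact grid recurrences that
  tie the cross map and its surrogates at skill 1, a sampling artifact
  rather than the pathology itself); and the classic Lorenz system
  ($\sigma = 10$, $\rho = 28$, $\beta = 8/3$; fixed-step 4th-order
  Runge–Kutta at $dt = 0.01$, 1000-step transient discarded).

What the generators do *not* emulate: real ecological data have unequal
sampling, missing values, non-Gaussian observation error, regime shifts, and
many interacting species. Passing tests on these toys shows that the methods
behave as documented under their stated assumptions and fail in the
documented ways when those assumptions break — not that any method is safe
on field data.

## The benchmarks

`run_fpr_experiment()` measures false-positive rates: 1000 simulated pairs
of independent islands, one surrogate test each, fraction rejected at
$\alpha = 0.05$. Phase randomization sits near its nominal level on the
stationary equilibrium model (a few percent) and inflates to roughly a fifth
of all pairs on random walks; permutation is grossly anticonservative on
both (half or more).

`run_noise_grid()` crosses process-noise and measurement-noise levels
(defaults 0/2/8 and 0/0.5/1 — the extremes being the levels at which
detection of the true link is disrupted) with methods
(`granger`, `ccm_main`, `ccm_alternative`) and driver regimes, classifies
each replicate into five outcomes — correct unidirectional, reversed,
bidirectional, none detected, data rejected — and emits machine-readable
tallies (`tally_report()`). The two CCM methods differ only in the
convergence-test variant, so one cross-map run per replicate serves both.
The five-category mapping is isolated in `classify_outcome()` and never
consults the ground truth when classifying a verdict pair. Desk-scale runs
default to 200 replicates per cell; the full-scale convention is 1000.

## Problem sizes and reproducibility

The shipped tests run the dependence experiments at full scale (1000
simulations) and the CCM property checks on single trials of 400–500 points
with 8 replicates per qualitative grid-cell contrast; these sizes give
Monte-Carlo standard errors comfortably inside the asserted bounds. All
randomness descends from integer seeds through a deterministic substream
hash, so every reported number is exactly reproducible.

## Known limitations

* The transfer-entropy surrogate null is an independence null, not the
  sharp Granger null (above).
* Phase-randomization surrogates assume circular stationarity; on short,
  strongly autocorrelated series the test runs slightly above its nominal
  level even when the process is stationary.
* CCM criterion 2 is uninformative for exactly periodic causers on
  commensurate sampling grids (surrogates tie the original); the shipped
  pathologies avoid the grid artifact deliberately, but real strictly
  periodic data would face it.
* Lag-order selection for the Granger tests is fixed-and-reported (default
  2, or 5 in the noise grid where the dynamics carry two driver
  frequencies). An optional BIC scan over orders 1–5 (`lag_order = "bic"`)
  exists, but fixed-plus-reported is the default because silent automation
  hides a modelling decision.
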