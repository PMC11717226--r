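---
title: "VARX Granger analysis: model, estimation, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VARX Granger analysis: model, estimation, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the model and
its assumptions, the numerical choices behind the estimator and the tests,
what the simulation studies generate and deliberately do not generate, and
the design decisions taken where more than one reasonable construction
existed.

## The model and its assumptions

The package fits the vector autoregressive model with exogenous input

$$ y(t) = \sum_{l=1}^{n_a} A(l)\,y(t-l) + \sum_{l=0}^{n_b-1} B(l)\,x(t-l) + e(t), $$

with endogenous variables $y(t) \in \mathbb{R}^{d_y}$, exogenous inputs
$x(t) \in \mathbb{R}^{d_x}$, and an innovation $e(t)$ assumed Gaussian,
i.i.d. over time, and uncorrelated across channels.  Three assumptions
matter for the statistics:

* **Equation-error convention.** The innovation enters the recursion, so
  the internal state is taken as directly observed.  Observation noise on
  a hidden state (the output-error convention, available in the package as
  a *simulator* only) breaks this; the consequences are explored by the
  structure study below.
* **Stationarity and whiteness of residuals.** The deviance statistic
  collapses a channel's evidence into one number that grows linearly with
  $T$; transients, edges, or nonstationarity inflate it and produce
  spurious links.  Nothing in the estimator protects against this.
* **Zero-mean signals.** The model carries no intercept.  `varx()`
  therefore centers every series by default (`demean = TRUE`, means taken
  over finite samples); pass `demean = FALSE` to fit raw signals that are
  already centered.

Lag conventions are pinned throughout: $A$ acts on $y(t-l)$ for
$l = 1..n_a$, $B$ on $x(t-l)$ for $l = 0..n_b-1$; tensors are stored
lag-major with row = target (`A[lag, target, source]`).  Pre-history
samples ($t \le 0$) are treated as zero by the simulators.  This warm-up
convention cannot leak into estimates because estimation independently
discards every sample without a complete observed history.

## Estimation

The lagged regression $Y = XH + E$ is solved through its normal equations
$R_{xx} = X^\top X$, $R_{xy} = X^\top Y$, accumulated per recording
segment and summed (so segment order is irrelevant).  A sample $t$
contributes if and only if $y(t)$, its $n_a$ endogenous lags, and its
$n_b$ exogenous lags are all finite and lie in one segment — missing
values and segment boundaries are handled by this single window rule.

* **Ridge weight `gamma`** (default 0, dimensionless): the solve is
  $\hat H = (R_{xx} + \gamma\,\mathrm{diag}(R_{xx}))^{-1} R_{xy}$, so each
  predictor is penalized relative to its own scale.  No automatic
  selection is performed — an appropriate $\gamma$ depends on $T/N$ and is
  the user's call (cross-validation over a grid of `gamma` values is
  straightforward with `varx()` in a loop).  The solver is a Cholesky
  factorization with a QR fallback; an explicit inverse is never formed,
  and a singular unregularized system is reported with the suggestion to
  set $\gamma > 0$.
* **Gaussian lag basis `n_basis`**: long input filters are represented as
  $B = W\underline{B}$ with `n_basis` Gaussian bumps, centers equally
  spaced over $0..n_b-1$ including both endpoints, standard deviation
  equal to the center spacing with a floor of 0.5 lag (so no column
  degenerates), and unit column maxima (so the diagonal ridge weighting
  stays meaningful across bases).  Centers and widths are not prescribed
  by theory; uniform coverage is the standard construction for temporal
  response functions.  With `n_basis = n_b` the basis is square and
  invertible and the fit reproduces the unconstrained estimate exactly —
  a property the tests exploit.
* **Degenerate inputs**: a predictor with zero variance after masking is
  excluded from the model and from testing with a warning (it carries no
  information and would make the unregularized system singular); a target
  with zero variance yields `NA` tests for that row rather than a failure.

## Inference

For every predictor block (each endogenous channel's $n_a$ lags, each
exogenous channel's $n_b$ — or `n_basis` — predictors) the reduced model
is solved by deleting rows/columns of the cached $R_{xx}, R_{xy}$; the
data are never re-scanned, and the tests verify that this equals a refit
from scratch.  The deviance $D = T\log(\hat\sigma^2_r/\hat\sigma^2_f)$ is
referred to $\chi^2_{n}$ with $n$ = number of removed parameters (under
basis compression the reduced model drops the `n_basis` compressed
predictors, and $n$ = `n_basis`, keeping the models nested).  The diagonal
of the endogenous test matrix treats a channel's own history like any
other predictor.

With $\gamma > 0$ the ridge bias is removed from the statistic:
$D' = T'\log(\hat\sigma^2_r/\hat\sigma^2_f) - b_r + b_f$ with
$b = \tfrac12\,\mathrm{diag}(R_{xe}^\top R_{xx}^{-1}
R_{xe})/\mathrm{diag}(R_{ee})$ and $T' = T - N$.  Three choices here were
genuinely open and are fixed as follows:

* $R_{xx}^{-1}$ in the bias term is the **raw** inverse, as the formula is
  written; a regularized-inverse variant is available behind
  `regularized_inverse = TRUE` for sensitivity checks.
* $T'$ uses the **full model's** $N$ for both bias terms, and $T'$ is used
  only when bias correction is active; at $\gamma = 0$ the plain deviance
  with $T$ applies.
* A de-biased deviance can come out slightly negative; it is clamped to 0
  (p = 1), the conservative direction.

Effect size is reported as $R^2 = 1 - \exp(-D/T)$ (figures usually plot
$R = \sqrt{R^2}$).  No multiple-testing correction is applied by default;
`granger_edges(..., adjust = "BH")` is the opt-in helper.

## What the simulation studies generate — and what they do not

The three studies are seeded, bit-reproducible, and define the package's
evidence that the machinery is calibrated.  They emulate Gaussian i.i.d.
innovations driving stable recursions — they do *not* emulate 1/f spectra,
nonstationarity, nonlinearity, shared measurement artifacts, or the
dimensionality of real recordings, so passing them demonstrates internal
statistical correctness, not robustness on real data.

**Recovery study** (`recovery_study`): one realization at $T = 1000$ of a
three-channel system with one standard-normal input ($n_a = 3$,
$n_b = 1$), random stable filters (endogenous coefficients drawn with
spread 0.15 and redrawn if the companion spectral radius reaches 0.95;
input coefficients standard normal).  Reported: elementwise
true-vs-estimated correlation and maximum absolute error.

**Calibration study** (`fdr_study`): 1000 replicates of a six-channel,
one-input model ($n_a = n_b = 2$, $T = 1000$), input coefficients standard
normal, endogenous coefficients $\pm 0.05$ with random sign (redrawn on
the rare unstable draw), and exactly two channels clamped to zero — one
endogenous self-history, one input channel.  The per-channel rejection
rate at $\alpha = 0.05$ estimates the false-positive rate on the null
channels and the power elsewhere.  A remark on the power side: the unique
contribution of a removed endogenous block in this design is
$\approx n_a \cdot 0.05^2$ per unit innovation variance (the input-driven
component of a channel is redundant given the input and the other
channels), so the deviance noncentrality is about 5–6 and per-channel
power sits near 0.5–0.65 — the study reports exactly what this
configuration can deliver.  Power 1 on every endogenous channel would
require coefficient magnitudes roughly 0.12 or larger at this $T$.  The
input channels, with standard-normal coefficients, are detected in
essentially every replicate.  The same study at $T = 300$, $N = 20$,
$\gamma = 0.1$ with `compare_uncorrected = TRUE` is the de-bias
validation: corrected p-values stay at the nominal rate while the plain
statistic is (mildly, at these sizes) anticonservative.

**Structure study** (`structure_study`): the two-channel system with a
one-directional coupling $y_1 \to y_2$ and a third variable $x$ that is a
common cause, a collider, or independent, generated under equation-error
or output-error conventions ($n_a = n_b = 3$, $T = 5000$, 500
replicates).  Magnitudes are not prescribed anywhere, so they are fixed
once: coupling 0.3 at lag 1, self-history $(0.3, 0.15, 0.05)$, collider
gain 0.5, innovation and observation noise at unit scale.  Two
constructions deserve their rationale:

* **The common cause drives both channels at lag 0 only** ($b_0 = 0.5$).
  If the shared drive were spread over several lags, $y_2$'s past would
  carry information about $y_1(t)$ beyond $y_1$'s own past the moment the
  drive is unobserved — the reverse-path null would be false by
  construction, and "drop the input" would mechanically produce spurious
  links.  With an instantaneous drive the reverse-path null holds exactly
  whether or not $x$ is offered to the model, which is the calibration
  property the study is meant to probe.  The delayed-drive regime is
  precisely the unobserved-common-cause failure mode, and it is the
  output-error arm (below) that exhibits it.
* **The collider taps the current states**, $x(t) = 0.5\,(y_1(t) +
  y_2(t)) + \text{noise}$.  A collider sampled only from lagged states is
  nearly harmless here, because all of its parents are already in the
  model's conditioning set; conditioning on a function of the *current*
  states is what induces the spurious dependence the study demonstrates.

Under output-error generation, the non-collider scenarios use the strict
hidden recursion (noise-free, driven only by $x$; with an unconnected
input this leaves pure observation noise, so those power numbers are
meaningful only qualitatively), while the collider arm drives the hidden
recursion with an unobserved innovation and adds observation noise —
otherwise the endogenous pair that is supposed to cause $x$ would carry no
signal at all.  One structural fact falls out of the analysis: whenever
the two channels share hidden-state information (common cause or
collider), a VARX fit of output-error data gains a *relative* residual
improvement from the other channel's past — it denoises the hidden state
— so the reverse-path test fires at any observation-noise level.  Only
the independent scenario is calibrated under output-error generation, and
that is the property the test suite asserts.

## Problem sizes and numerical tolerances

The test suite runs the calibration and de-bias studies at their full
1000 replicates and the structure studies at 500; property checks use
$T \le 300$, $N \le 30$ with agreement thresholds of $10^{-8}$ (relative)
against dense least squares and $10^{-10}$–$10^{-12}$ for algebraic
identities.  The factored-response comparison ($H = (I-A)^{-1}B$ versus a
direct 40-lag moving-average estimate) uses $T = 10^5$ and requires
agreement within 10% of the peak response.  The large-model variant of
the calibration study ($d_y = 60$) is available by argument
(`fdr_study(d_y = 60)`) but is not part of the default runs.

## Known limitations

* No stability enforcement: an unstable estimated $A$ only matters when
  computing $H$, where it is detected and reported, never repaired.
* No automatic choice of $n_a$, $n_b$, or $\gamma$; no L1/elastic-net or
  state-space regularization; no frequency-domain decomposition of the
  Granger statistics; no estimation (as opposed to simulation) of the
  output-error model.
* The deviance inherits all fragility of its i.i.d.-innovation
  assumption; with nonstationary data, the estimates of $A$, $B$, and
  $R^2$ remain valid linear-prediction summaries but the analytic
  p-values do not.
* Diagonal entries of $A$ act as high-pass corrections whenever real
  signals have 1/f-like spectra; individual delays on the diagonal should
  not be interpreted literally.
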