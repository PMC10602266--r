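---
title: "Intrinsic-frequency analysis and its neural surrogate: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic-frequency analysis and its neural surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifpulse)
```

## The model

The intrinsic-frequency (IF) method models one cardiac cycle of an arterial
pressure waveform $p(t)$, $0 \le t \le T$, as two constant-envelope
sinusoids joined at the dicrotic notch $T_0$ (aortic valve closure): a
systolic regime driven by the coupled heart--aorta system, rotating at
angular frequency $\omega_1$, and a diastolic regime driven by the
decoupled arterial tree at $\omega_2$. The parameters minimize

$$
\left\lVert\, p(t)
 - \chi_{(0,T_0)}\!\left[a_1\cos\omega_1 t + b_1\sin\omega_1 t\right]
 - \chi_{(T_0,T)}\!\left[a_2\cos\omega_2 t + b_2\sin\omega_2 t\right]
 - c \,\right\rVert_2^2
$$

subject to **continuity** at the notch and **periodicity** over the cycle:

$$
a_1\cos\omega_1 T_0 + b_1\sin\omega_1 T_0
  = a_2\cos\omega_2 T_0 + b_2\sin\omega_2 T_0,
\qquad
a_1 = a_2\cos\omega_2 T + b_2\sin\omega_2 T .
$$

The equivalent phase form writes each regime as $R\sin(\omega t + \varphi)$
with envelopes $R_s, R_d \ge 0$ and initial phases $\varphi_1, \varphi_2$;
the envelope ratio $ER = R_s/R_d$ is a derived index. The model's key
assumptions are that the instantaneous frequency is piecewise constant
with a single step at $T_0$, that the envelopes are constant within each
regime, and that the notch time is known (supplied by the acquisition
pipeline, never inferred here).

All computation happens in a dimensionless **standard form**: values
min--max normalized to $[0,1]$, time normalized to a unit cycle, 500
uniform samples. Scaled parameters (written with hats) relate to the
dimensional ones by $\hat\omega_i = \omega_i T$,
$\hat c = (c - P_{\min})/(P_{\max} - P_{\min})$,
$\hat R = R/(P_{\max} - P_{\min})$, $\hat T_0 = T_0/T$, with phases
unchanged; `normalize_parameters()` / `denormalize_parameters()` implement
the exact bijection. Scaled frequencies are **radians per cardiac cycle**
throughout the computational core. This radian semantics is forced by the
analytic completion formula below, which uses $\hat\omega_2\hat T_0$ and
$\hat\omega_2$ directly as sine arguments. Published physiological ranges
for $\hat\omega_1$ (tens to ~155) imply strongly oscillatory standard-form
shapes under this reading; since the display convention behind those
printed numbers is not stated by the sources that report them, the package
takes the radian semantics as authoritative and supports both regimes: the
generator's `"table3"`/`"table2"` presets sample the printed ranges as
radians, and a `"smooth"` preset (frequencies of a few radians per cycle)
produces the slowly oscillating shapes familiar from pulse-wave figures.
Nothing in the algorithms depends on which regime is used.

## Waveform preparation

`prepare_waveform()` applies, in order: min--max amplitude normalization,
time normalization, natural-cubic-spline resampling onto
$\tau_k = k/499$, and one final min--max pass. Choices worth recording:

* **Order of operations.** Whether resampling should precede or follow
  normalization is not fixed by the method itself; this package normalizes
  first and renormalizes after the spline, which guarantees the exact
  $[0,1]$ invariant regardless of spline overshoot.
* **Grid convention.** The 500 samples include both endpoints $\tau = 0$
  and $\tau = 1$ (step $1/499$), so periodicity can be checked on the grid
  itself. The same convention is used everywhere (generator, solver,
  surrogate inputs); consistency matters more than the choice.
* **Spline boundary behavior.** Natural cubic spline, no extrapolation.
  An input grid that stops short of $\tau = 1$ by more than half its mean
  spacing is padded by repeating the last sample at $\tau = 1$ (a periodic
  cycle ends where it began); smaller shortfalls snap the last knot to 1.
* **Numerical invariances.** Preparation is invariant to affine value
  changes and time rescalings up to floating-point rounding (about
  $10^{-13}$ relative; the test suite asserts $10^{-12}$), and idempotent
  on standard-form inputs.

## The optimization-based solver

With $(\hat\omega_1, \hat\omega_2)$ fixed, the discrete objective -- the
sum of squared residuals over the 500 grid points -- is quadratic in
$(a_1, b_1, a_2, b_2, c)$ and both constraints are linear, so the inner
problem is an equality-constrained least-squares solve.
`fit_linear_given_frequencies()` computes its exact minimizer by
projecting onto an orthonormal nullspace basis of the constraint matrix
(QR) and solving the reduced $3$-parameter problem; the C++ grid scan used
by `solve_if()` reaches the same minimizer through closed-form elimination
of $a_1, b_1$ and reduced $3\times3$ normal equations, reusing
per-frequency trigonometric moments so a full rectangle of frequency
pairs costs $O(n_{\text{grid}} \cdot 500 + n_{\text{pairs}})$. The two
routes are cross-checked against each other and against a dense KKT solve
in the tests.

`solve_if()` scans a configurable rectangle (presets: `paper_range`,
$[40,200]\times[10,200]$ rad/cycle, generously covering the published
scaled ranges; `smooth`, $[2,20]\times[1,12]$) at a coarse step of 1
rad/cycle, then refines locally: three levels, each dividing the step by
10 (final resolution $10^{-3}$ rad/cycle), each spanning two previous
steps per side of its incumbent. Two robustness choices came out of
observed failure modes on synthetic data:

* **Multi-start refinement** (`refine_starts`, default 5): the discretized
  objective is multimodal, and in roughly a few percent of cases the best
  coarse node sits in a shallow spurious basin while the true basin's
  coarse node ranks second or third. Refining the best few separated
  coarse local minima and keeping the overall optimum removes these
  misses at negligible cost (~5k extra inner solves against ~30k for the
  coarse scan).
* **Window width of two previous steps**: the objective valley is curved
  in $(\hat\omega_1, \hat\omega_2)$; an incumbent can land at the edge of
  its cell, and a one-step window then excludes the valley floor at the
  next level.

Ties on the objective break toward the lexicographically smaller frequency
pair (the scan iterates in ascending order with strict improvement).
Degenerate geometry is handled, not hidden: $|\sin\hat\omega_1\hat T_0| <
10^{-8}$ switches the elimination to a generic nullspace solve, and a
rank-deficient reduced design (a regime that is numerically constant)
returns a flagged minimum-norm solution with a warning rather than an
error. The solver itself has no noise model; robustness to measurement
noise is the surrogate's concern via its training data.

## Analytic completion and conversions

Given the five parameters $(\hat\omega_1, \hat\omega_2, \hat R_s,
\hat\varphi_1, \hat T_0)$, the diastolic pair follows analytically from
the two constraints on the unit cycle:

$$
\hat\varphi_2 = \operatorname{atan2}\!\big(
  \sin\hat\varphi_1\sin(\hat\omega_2\hat T_0)
  - \sin(\hat\omega_1\hat T_0 + \hat\varphi_1)\sin\hat\omega_2,\;
  \sin(\hat\omega_1\hat T_0 + \hat\varphi_1)\cos\hat\omega_2
  - \sin\hat\varphi_1\cos(\hat\omega_2\hat T_0)\big),
\qquad
\hat R_d = \frac{\hat R_s \sin\hat\varphi_1}{\sin(\hat\omega_2 + \hat\varphi_2)} .
$$

`recover_diastolic()` canonicalizes to $\hat R_d \ge 0$ using the
$(R,\varphi) \sim (-R, \varphi + \pi)$ identification and reduces phases
to $(-\pi, \pi]$. Its output satisfies both constraint residuals to
machine precision (asserted at $10^{-9}$). Degeneracies are explicit:
$|\sin(\hat\omega_2 + \hat\varphi_2)| < 10^{-10}$ would make the envelope
unbounded, and $\sin\hat\varphi_1 = 0$ with a nonzero continuity
requirement has no solution; both raise (or, for the generator and the
surrogate, flag) rather than returning garbage. The phase--Cartesian
conversion uses the two-argument arctangent with $a = R\sin\varphi$,
$b = R\cos\varphi$; the one-argument $\tan^{-1}(a/b)$ form is
quadrant-ambiguous and would break the identity
$a\cos\omega t + b\sin\omega t = R\sin(\omega t + \varphi)$ in two of the
four quadrants.

## The synthetic generator

`generate_dataset()` supplies the exact-ground-truth data on which the
surrogate is trained and validated. Six parameters are sampled --
uniformly at random or on a near-uniform mesh -- inside rectangular
intervals; each tuple is completed analytically, so the stored parameters
satisfy the constraints exactly, and the waveform is the analytic
reconstruction on the standard grid.

* **Ranges.** The `"table3"` preset carries the published physiological
  ranges of the five scaled parameters for carotid waveforms
  ($\hat\omega_1 \in [75.0, 155.2]$, $\hat\omega_2 \in [19.2, 71.3]$,
  $\hat R_s \in [0.43, 0.89]$, $\hat\varphi_1 \in [-1.269, -0.008]$,
  $\hat c \in [0.18, 0.58]$); `"table2"` the analogous generalization-set
  ranges. **No published range exists for $\hat T_0$**; the default
  $[0.30, 0.45]$ is this package's choice of a typical systolic fraction
  of the cardiac cycle.
* **Validity filters.** Completed tuples are rejected when the geometry is
  degenerate, when $\hat R_d > 4\,\hat R_s$ (the periodicity constraint
  can make the diastolic envelope arbitrarily large; physiological
  envelope ratios are of order one, and without the cap a heavy tail of
  extreme shapes dominates), or when reconstructed values leave
  $[-0.25, 1.25]$. About a quarter of raw draws in the `table3` box
  survive all filters.
* **No re-normalization.** Generated waveforms keep their analytic values.
  Re-min-max-normalizing them would silently change $\hat R_s$ and
  $\hat c$ away from the stored ground truth; the value-band filter keeps
  shapes near the standard band instead. Consequently generated waveforms
  span approximately, not exactly, $[0,1]$ -- a deliberate trade of
  cosmetic exactness for truthful labels.
* **Pairwise regions.** Joint 2-D physiological regions for parameter
  pairs are not published; the generator therefore uses the rectangle
  plus optional user-supplied linear pairwise constraints
  (e.g. $\hat\omega_1 - \hat\omega_2 \ge 0$), defaulting to none, rather
  than inventing region boundaries. Whether the original mesh was jointly
  uniform over all six axes or per-pair is likewise unstated; the mesh
  mode here is jointly uniform with near-equal points per axis.
* **Noise.** Optional additive Gaussian noise (default off) supports
  robustness experiments; ground-truth labels always describe the
  noise-free waveform.

What the generator does *not* emulate: device-specific noise and
artifacts, beat-to-beat variability, baseline drift, multi-cycle signals,
or notch-detection error. Tests passing on this synthetic population
therefore demonstrate correctness of the algorithms and the achievable
accuracy of the surrogate *under the model*, not clinical performance on
measured waveforms.

## The surrogate network

The surrogate is a sequentially-reduced feedforward network: input
$[\hat T_0, \text{500 samples}] \in \mathbb{R}^{501}$, hidden widths
halving per layer ($W_l = W_1/2^{l-1}$), Swish activations
($x\,\sigma(x)$), affine output layer, five outputs in the fixed order
$(\hat\omega_1, \hat\omega_2, \hat R_s, \hat\varphi_1, \hat c)$ (the
output set is standard; the order is this package's convention). The
remaining parameters come from `recover_diastolic()`, so **every
prediction satisfies the model constraints exactly** -- the network never
has to learn the constraint manifold.

Training choices, with defaults and reasons:

* **Loss**: MSE on feature-scaled targets (per-output standardization by
  training-set mean and SD, inverted at prediction). Scaling is fitted on
  training targets only; validation and test data never leak into it.
* **Regularization**: L1 or L2 penalty on weights, coefficient $\lambda$;
  biases are excluded (standard practice -- penalizing biases shifts
  predictions without controlling capacity).
* **Optimizer**: Adam, learning rate $10^{-3}$ (the conventional default
  for this task family), $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-7}$; shuffled mini-batches of 64.
* **Initialization**: Glorot-uniform per restart.
* **Restarts**: each restart re-initializes weights *and* re-shuffles
  batches under a seed derived from the master seed, and the restart with
  the lowest validation MSE wins. Default 10 restarts; desk-scale
  experiments use 3.
* **Epochs and stopping**: up to 500 epochs with early stopping (patience
  50) by default; stopping restores the best-validation-epoch weights.
  Epoch budget and batch size are not externally prescribed anywhere, so
  they are declared package defaults, fully configurable.
* **Grid search**: `fnn_grid_search()` enumerates the 54-point design
  space $L \in \{3,4,5\} \times W_1 \in \{128,256,512\} \times
  \{L_1,L_2\} \times \lambda \in \{10^{-5},10^{-6},10^{-7}\}$ (or any
  subset) and selects the validation argmin. The selected published
  architecture -- $L = 4$, widths 256/128/64/32, L2 with
  $\lambda = 10^{-6}$ -- is the default of `fnn_config()`.

## The reference experiment and problem sizes

`run_surrogate_experiment()` is the package's reproducible end-to-end
run: sample training, validation, and blind datasets in the `table3`
ranges (the blind set under its own derived seed), train the default
architecture, and score blind predictions against the exact generating
parameters. Sizes are 6000/600/600 with 3 restarts of up to 150 epochs
(patience 20) -- a desk-scale rendition of the published design that
keeps a full run in the ten-minute range on one CPU while leaving
accuracy margins wide. The 600-record validation and blind sizes mirror
the published split; the published synthetic pool size (8208) is the
generator's default `n` for standalone use. On this experiment the
surrogate's blind-set RMSEs are several times smaller than the published
clinical blind-test values (unsurprising: the synthetic blind set is
noise-free and in-distribution), and per-parameter correlations exceed
0.99; the acceptance script recomputes these quantities from scratch.

A deliberately scaled-down experiment (300/60/60 records, a 64-wide
3-layer network) appears in examples and the README; its errors are an
order of magnitude larger, which is the expected sample-size effect, and
`sensitivity_curve()` exposes exactly this dependence on nested subsets
of a fixed training pool against a fixed validation population.

## Agreement statistics

`agreement_report()` compares two parameter tables column-wise: RMSE,
Pearson correlation with the $t$-transform p-value ($n-2$ degrees of
freedom), Bland--Altman bias with $\pm 1.96\,\mathrm{SD}$ limits of
agreement (sample SD), absolute-error histograms (30 equal-width bins
over $[0, \max|e|]$), and two relative errors:

* **Ensemble relative error** $= 100 \cdot \mathrm{RMSE} /
  \overline{|y|}$. The published error tables pair an RMSE with a
  percentage in exactly this ratio, but no formula is printed there;
  this definition is an inference, implemented in one place
  (`ensemble_relative_error()`) so it can be swapped.
* **Point-wise average relative error** $= 100 \cdot
  \operatorname{mean}(|e_i|/|y_i|)$, excluding zero-truth samples with a
  warning and a reported count. Also an inferred definition, likewise
  isolated.

All statistics are verified against brute-force recomputation and, for
the correlation, against `stats::cor.test()`.

## Degenerate inputs, tolerances, tie-breaks

* Flat waveforms (zero range) are rejected at normalization; a flat
  *fit* (zero amplitudes, $c$ = mean) is legal solver output.
* Constraint residual assertions use $10^{-9}$; the analytic completion
  and the constrained inner solve are exact to rounding, so this is a
  loose ceiling, not a tuned constant.
* Degeneracy thresholds: $10^{-10}$ on $|\sin(\hat\omega_2 +
  \hat\varphi_2)|$ (envelope blow-up), $10^{-8}$ on
  $|\sin\hat\omega_1\hat T_0|$ (elimination pivot).
* Systole is the half-open interval $[0, \hat T_0)$; with continuity
  enforced the choice is value-neutral but fixes sample bucketing.
* Master seeds fan out to stage seeds through a fixed integer map
  (`seed * 7919 + 104729 * stage mod 2^31 - 1`), so stages are
  independently reproducible.

## Limitations

The IF model itself is a two-regime, constant-envelope idealization; more
regimes (multiple decoupling times) and time-varying envelopes are out of
scope. The surrogate is trained and evaluated here on synthetic data
only: clinical accuracy claims require clinical waveforms, which this
package does not ship. Notch detection, beat segmentation, and denoising
are upstream concerns. The brute-force solver's default resolution
($10^{-3}$ rad/cycle) and search rectangles are engineering choices, not
reproductions of any published solver configuration, and frequency
recovery guarantees in the tests refer to the filtered synthetic
population described above.
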