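# ifpulse

Intrinsic-frequency (IF) analysis of single-cycle arterial pressure
waveforms, and a feedforward neural-network surrogate that replaces the
expensive non-convex IF optimization with a millisecond forward pass.

## The problem

The IF method extracts physiologically meaningful dynamics from one
cardiac cycle of an arterial (e.g. carotid) pressure waveform by fitting
a piecewise sinusoid with two regimes: systole, where the heart and aorta
are coupled and oscillate at an intrinsic frequency ω₁, and diastole,
where the aorta is decoupled after aortic valve closure (the dicrotic
notch, time T₀) and rings at a second frequency ω₂. The fit minimizes

    ‖ p(t) − χ(0,T0)[a₁cos ω₁t + b₁sin ω₁t]
           − χ(T0,T)[a₂cos ω₂t + b₂sin ω₂t] − c ‖²₂

subject to continuity at the notch and periodicity over the cycle, and is
non-convex in (ω₁, ω₂) — the standard solver is a brute-force scan over a
frequency rectangle with an exact constrained linear solve at each node,
which takes seconds per waveform. That cost blocks real-time use, which
is where the surrogate comes in: a sequentially-reduced feedforward
network (hidden widths halving layer by layer) maps a normalized
waveform plus its notch time directly to the five scaled IF parameters
(ω̂₁, ω̂₂, R̂ₛ, φ̂₁, ĉ); the remaining diastolic parameters follow
analytically from the two constraints, so every prediction satisfies the
model exactly.

The package implements the whole workflow in tidyverse style (data
frames in, tibbles out, `tidy()`/`glance()`/`autoplot()` methods):

* **Waveform preparation** — min–max normalization, unit-cycle time
  scaling, natural-cubic-spline resampling to the 500-sample standard
  form (`prepare_waveform()`).
* **Optimization-based solver** — coarse frequency scan plus multi-start
  local refinement, with the constrained inner solve done exactly
  (`solve_if()`, `fit_linear_given_frequencies()`).
* **Synthetic generator** — waveforms with exact ground-truth parameters
  sampled in published physiological ranges, for training and validation
  (`generate_dataset()`).
* **Surrogate** — training with Adam, restarts, early stopping, and the
  54-combination hyperparameter grid search (`fnn_train()`,
  `fnn_grid_search()`, `predict()`).
* **Evaluation** — RMSE, ensemble and point-wise relative errors, Pearson
  correlation, Bland–Altman limits of agreement, error histograms
  (`agreement_report()`), and training-size sensitivity
  (`sensitivity_curve()`).
* **CLI** — `inst/cli/ifpulse` exposes `solve`, `synth`, `train`,
  `predict`, `eval`, `sensitivity`, and an end-to-end `pipeline`.

## Worked example

Fit the IF model to a simulated slowly oscillating pulse recorded in
arbitrary units at 120 samples over a 0.82 s cycle, notch at 0.31 s:

```r
library(ifpulse)

t <- seq(0, 0.82, length.out = 120)
v <- 78 + 42 * exp(-3 * t) * sin(pi * t / 0.82)^2 + 6 * sin(2 * pi * t / 0.82)
w <- raw_waveform(t, v, cycle_duration = 0.82, notch_time = 0.31)

s <- prepare_waveform(w)
s
#> <scaled_waveform: 500 samples on [0, 1], notch at 0.3780, range [0.000, 1.000]>

fit <- solve_if(s, solver_config("smooth"))
fit
#> <if_fit: omega1_hat = 7.491, omega2_hat = 5.332, RMS residual = 9.67e-03 (24213 grid evals)>

tidy(fit)
#> # A tibble: 9 × 2
#>   term       estimate
#>   <chr>         <dbl>
#> 1 omega1_hat    7.49
#> 2 omega2_hat    5.33
#> 3 Rs_hat        0.463
#> 4 Rd_hat        0.556
#> 5 phi1_hat     -0.934
#> 6 phi2_hat      0.219
#> 7 c_hat         0.548
#> 8 T0_hat        0.378
#> 9 ER_hat        0.832
```

The fitted scaled frequencies are in radians per cardiac cycle: this
waveform swings about 7.5 rad/cycle during systole and 5.3 rad/cycle
during diastole, with envelope ratio ER ≈ 0.83 and an RMS reconstruction
residual of about 1% of the waveform range. `autoplot(fit)` overlays the
reconstruction and the notch position on the waveform.

A scaled-down surrogate experiment (300 training waveforms, 64-wide
3-layer network) runs in under a minute and already tracks the solver's
parameters; accuracy at this size is limited by training data, an effect
`sensitivity_curve()` quantifies:

```r
ex <- run_surrogate_experiment(
  seed = 1, n_train = 300, n_validation = 60, n_blind = 60,
  config = fnn_config(hidden_layers = 3, first_width = 64,
                      epochs = 60, restarts = 1, patience = 15))
ex$report[, c("parameter", "rmse", "pearson_r")]
#> # A tibble: 5 × 3
#>   parameter    rmse pearson_r
#>   <chr>       <dbl>     <dbl>
#> 1 omega1_hat 7.21       0.951
#> 2 omega2_hat 8.56       0.860
#> 3 Rs_hat     0.0636     0.651
#> 4 phi1_hat   0.111      0.951
#> 5 c_hat      0.0251     0.969
```

The full-scale experiment below is an order of magnitude more accurate.

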