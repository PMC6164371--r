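# vrfrap

Variable-radius FRAP analysis of anomalous and confined membrane diffusion.

## What problem this solves

Fluorescence recovery after photobleaching (FRAP) measures the lateral
mobility of membrane molecules: fluorophores inside a spot of radius *R*
are irreversibly bleached by a laser pulse and the refilling of the spot is
recorded over time. On cell membranes the recovery of a membrane-bound
protein is rarely pure Brownian, and a *single-spot* experiment cannot tell
two very different physical pictures apart:

* **CTRW anomalous subdiffusion (aDm)** — hopping between traps with
  heavy-tailed waiting times, ⟨r²(t)⟩ ∝ t^α with α < 1;
* **restricted Brownian motion (rBm)** — normal diffusion of a mobile pool
  plus a fraction confined in nanodomains (e.g. cytoskeleton fences).

Both fit a single recovery curve almost equally well. Repeating the
experiment at several bleach radii and regressing the fitted parameters
against 1/R separates them:

* CTRW-like motion gives a **negative** slope of fitted α vs 1/R, and the
  intercept at 1/R → 0 recovers the true α and D (correcting the
  systematic finite-size underestimation of single-spot fits);
* domain confinement gives a **positive** slope of the mobile fraction
  M vs 1/R, and the empirical confinement law
  `M = Mp + 0.63·L/R` (valid for L < R) yields the domain radius L and
  the free fraction Mp.

The package provides, for people analysing (or simulating) such
experiments:

* an event-driven Monte-Carlo simulator of CTRW subdiffusion in a bounded
  disk with Gaussian-profile photobleaching (`ctrw_config()`,
  `simulate_recovery()`, `compute_msd()`), with Lévy waiting times
  τ = (1−u)^(−1/α) − 1 and jumps of total variance 2D;
* the three closed-form recovery models as alternating series in the
  bleach constant K (`adm_recovery()`, `bm_recovery()`, `rbm_recovery()`,
  `bleach_profile()`, `dispersion_from_alpha()`);
* bounded nonlinear least-squares fitting with χ² model comparison
  (`fit_recovery()`, `compare_models()`, broom-style `tidy()`/`glance()`);
* the variable-radius inference (`fit_vr_series()`,
  `regress_vs_inverse_radius()`, `extrapolate_parameter()`,
  `classify_motion()`, `schram_domain_size()`,
  `alpha_crossover_radius()`);
* a synthetic-experiment generator emulating a confocal acquisition
  (150 samples / 100 s dual-rate grid, four objective calibrations,
  additive noise): `generate_vrfrap_dataset()`, `instrument_table()`;
* plain-text curve files and JSON reports (`write_frap_curve()`,
  `write_report()`) plus a thin command-line wrapper
  (`inst/scripts/vrfrap-cli.R` with `simulate`, `generate`, `fit`,
  `vrfrap` subcommands).

## Worked example

Generate a synthetic variable-radius dataset from a confined-diffusion
truth (free fraction Mp = 0.75, domain radius L = 0.09 µm, D = 0.22 µm²/s,
K = 1.2, 3 replicates per objective radius, 3% intensity noise), fit every
curve with the restricted Brownian model, regress M against 1/R and invert
the confinement law:

```r
library(vrfrap)

ds <- generate_vrfrap_dataset(
  "rbm", list(K = 1.2, D = 0.22, Mp = 0.75, L = 0.09),
  replicates_per_radius = 3, noise_sd = 0.03, seed = 1
)
series <- fit_vr_series(ds, "rbm")
reg <- regress_vs_inverse_radius(series, "M")
reg
#> <vr_regression: M ~ 1/R> slope = 0.05823 (se 0.00475), intercept = 0.7469 (se 0.0116), r2 = 0.938, n = 12

classify_motion(NULL, reg)
#> [1] "domain_confined"

schram_domain_size(reg)
#> # A tibble: 1 × 6
#>        L L_stderr    Mp Mp_stderr confined_fraction valid
#>    <dbl>    <dbl> <dbl>     <dbl>             <dbl> <lgl>
#> 1 0.0924  0.00754 0.747    0.0116             0.253 TRUE
```

The positive, significant M-vs-1/R slope classifies the motion as
domain-confined, and inverting `M = Mp + 0.63·L/R` recovers the truth
within the noise: domain radius L ≈ 0.092 µm (true 0.09), free fraction
Mp ≈ 0.747 (true 0.75), i.e. ~25% of molecules confined in ~90 nm
domains. `autoplot(reg)` draws the regression with its 1/R = 0 intercept.

The CTRW side of the same logic: simulate recoveries at radii 1–3 a.u.
(`simulate_recovery()`), fit each with the anomalous series
(`fit_vr_series(curves, "adm")`), and extrapolate fitted α and D to
1/R = 0 with `regress_vs_inverse_radius(..., r_min = 1)` and
`extrapolate_parameter()`.

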