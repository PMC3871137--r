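---
title: "Methods: NIR calibration and degradation kinetics for jujube vitamin C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration and degradation kinetics for jujube vitamin C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jujubeNIR)
```

## The problem

Vitamin C (ascorbic acid) is the key quality index of fresh jujube
(*Ziziphus jujuba*) and declines sharply during room-temperature storage.
Reference determination is destructive (2,6-dichloroindophenol titration),
so a fruit can be measured chemically only once. FT-NIR spectroscopy offers
a non-destructive surrogate: this package implements the full chain from
absorbance spectra to a vitamin C calibration, a degradation-kinetics
model, and a spectra-only estimate of storage time and remaining shelf
life.

The study design the package targets (and which its synthetic generator
reproduces) is longitudinal with destructive sampling: 72 fruits in 18
groups of 4 are stored at 20 °C; every surviving fruit is scanned daily
(12,000–4,000 cm⁻¹ at 8 cm⁻¹ steps, three probe positions averaged), and
one group is titrated per day for 18 days. Group *k* therefore contributes
*k* daily spectrum sets before being destroyed, and chemistry over time is
observed *across* fruits, never within one.

## Pipeline

1. **Replicate averaging** — the three probe positions of a fruit-day are
   averaged point-wise (`average_replicates()`).
2. **Pretreatment** (`pretreat()`) — one of: raw, Savitzky–Golay smoothing,
   multiplicative scatter correction (MSC), or first/second S–G
   derivatives.
3. **Region restriction** (`restrict_region()`) — VNIR (4,000–12,000),
   SW-NIR (9,091–12,000) or LW-NIR (4,000–9,091 cm⁻¹), closed intervals.
4. **Hold-out split** (`split_samples()`) — decayed fruits are excluded,
   then 50 calibration / 17 prediction fruits are drawn at random.
5. **Wavelength selection** (`select_wavenumbers_rc()`) — regression-
   coefficient (RC) selection, below.
6. **MLR calibration** (`fit_mlr()`) — ordinary least squares of titrated
   vitamin C on the selected absorbances; metrics Rc/RMSEC (calibration)
   and Rp/RMSEP (prediction) via `evaluate_calibration()`.
7. **Kinetics** (`fit_zero_order()`, `fit_first_order()`,
   `compare_kinetics()`) — zero-order vs first-order degradation of the
   titrated contents against storage time, using NIR-predicted initial
   contents.
8. **Shelf life** (`shelf_life_from_spectra()`, `safe_storage_time()`) —
   inversion of the zero-order law for storage time, and the time at which
   the modeled content crosses a threshold.

`run_pipeline()` sequences all stages with one reproducible configuration;
`inst/cli/jujube-nir.R` is a thin shell front-end over the same functions.

## Models and estimators

**MLR calibration.** With absorbances \(X_1,\dots,X_p\) at the selected
wavenumbers, \(VCC = b_0 + \sum_i b_i X_i + \varepsilon\), fitted by OLS.
We report Pearson correlation (not \(R^2\)) and RMSE with denominator
\(n\), the conventions of NIR calibration tables. The 95% confidence
interval attached to a model is for the *mean* fitted value,
\(\bar y \pm t_{0.975,\,n-p-1}\, s/\sqrt n\) — the single-interval summary
customarily reported alongside such calibrations. Per-sample prediction
intervals are out of scope.

**RC wavelength selection.** The field's RC method is defined only
operationally in most reports; we implement the standard reading: compute
a full-spectrum coefficient vector on centered data by ridge-stabilized
least squares, \(\hat\beta = (X_c'X_c + \lambda I)^{-1}X_c'y_c\) with
\(\lambda = 10^{-3}\,\mathrm{tr}(X_c'X_c)/p\) (the stabilization is
required because \(p \gg n\); the trace scaling makes \(\lambda\)
unit-free), find the local maxima of \(|\hat\beta|\) along the wavenumber
axis, and keep the `n_select` largest. Ties in \(|\hat\beta|\) go to the
lower wavenumber, and candidates at the grid ends qualify against their
single neighbour — both rules exist purely to make selection
deterministic.

**Degradation kinetics.** Zero order is fitted as the three-parameter
regression \(VCC = a + b\,VCC_0 - Kt\) on (intercept, predicted initial
content, storage time); the textbook two-parameter law \(C = C_0 - Kt\)
is available as the `textbook = TRUE` special case (\(a=0, b=1\)). First
order, \(VCC = C_0 e^{-Kt}\), is fitted by Levenberg–Marquardt nonlinear
least squares; a log-linear regression on the positive responses supplies
the starting values only. We do not estimate by log-linearization because
it is biased under additive measurement noise. Model choice is by larger
correlation between observed and fitted values, ties to the simpler
zero-order form.

Initial contents \(VCC_0\) for fruits titrated on day \(d > 1\) are not
observable (destructive design); they are predicted by applying the NIR
calibration to each fruit's day-1 spectrum. Storage time is
\(t = \mathrm{day} - 1\): day 1 is the arrival state.

**Shelf life.** The zero-order line is inverted algebraically,
\(t = (a + b\,VCC_0 - VCC)/K\), which round-trips with the forward model
to machine precision. A second, `as_printed`, inversion evaluates the
literal published coefficients \(t = 17.128 - 0.002\,VCC_0 -
0.046\,VCC\); because those are rounded, it is *not* the exact inverse of
the published zero-order model (at \(VCC_0 = VCC = 0\) the two give
17.128 vs \(338.787/20.677 \approx 16.385\) days). Both are exposed
behind an explicit `method` flag, default algebraic. A negative estimated
storage time (day-t spectra implying more vitamin C than day 0) is
returned with a flag, never clamped. `safe_storage_time()` uses threshold
0 mg/100 g by default — "shelf life ends when the vitamin C pool is
exhausted" is a modeling convention, not a safety standard, so the
threshold is a parameter.

## The synthetic study generator

No spectra or titration data were deposited with the study this design
follows, so validation rests on a generator whose defaults *are* the
study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_fruits`, `n_groups`, `group_size` | 72, 18, 4 | destructive design |
| `n_positions` | 3 | probe replicates per fruit-day |
| `vcc0_mean`, `vcc0_sd` | 350, 40 mg/100 g | truncated-normal initial content |
| `rate_K`, `kinetic_form` | 20.677, zero | generating decay law |
| `band_sd` | 60 cm⁻¹ | Gaussian band width |
| `scatter_slope_sd` | 0.05 (log) | multiplicative scatter |
| `scatter_offset_sd` | 0.02 AU | additive scatter |
| `noise_sd` | 0.003 AU | white measurement noise |
| `decay_start_day`, `decay_prob_per_day` | 12, 0.045 | late-storage decay hazard |
| `n_decayed` | 5 | conditioned decayed-fruit count |
| `titer_T`, `dilution_A`, `assay_weight`, `blank_V0` | 0.2, 10, 10, 0.1 | assay constants |
| `titration_noise_sd` | 5 mg/100 g | titration repeatability |

A spectrum is \(s\,[c_0(w) + d(w)\,vcc] + o + \epsilon(w)\): smooth
baseline plus Gaussian bands, with the amplitudes of the five bands at
8,330, 6,900, 5,666, 5,150 and 4,060 cm⁻¹ affine in the vitamin C
content and fixed water-dominated bands at 10,300 and 4,710 cm⁻¹. All
five informative bands are vitamin-C-coupled so that RC selection has a
well-defined recoverable ground truth in the LW-NIR region. The
multiplicative slope is log-normal (a slope must stay positive), the
offset and noise Gaussian. The initial-content distribution (mean 350,
sd 40) is consistent with the published sample range of roughly 3–398
mg/100 g once 17 days of decay at 20.7 mg/100 g/day are applied.

Decay: fruits become at-risk on day 12 with a per-day Bernoulli hazard,
and decayed fruits get 10× inflated spectral noise from their decay day
onward (emulating the disordered late-storage spectra). The default
conditions the *number* of decayed fruits on exactly 5 — the documented
loss of the emulated study — by drawing which fruits decay with
probability proportional to their at-risk exposure and the decay day from
the correspondingly truncated geometric; `n_decayed = NULL` gives the
unconditioned hazard. The default hazard 0.045/day makes the
unconditioned expectation also ≈ 5.

Titration records are generated by inverting the assay arithmetic
\(VCC = (V - V_0)\,T\,A/W \times 100\) from the true content plus
measurement noise, so at zero noise evaluating the assay on a generated
record recovers the truth exactly. The assay constants are conventional
magnitudes (no values were published); they are configuration, not
science.

**What the generator does not emulate:** real radiative transfer (bands
are Gaussian, scatter is exactly affine — which is why MSC removes it
exactly), temperature dependence (the study is fixed at 20 °C),
instrument drift, and biological covariance between fruit size and
chemistry. Passing tests on synthetic data therefore demonstrate the
*estimators* (selection recovers planted structure, rates are recovered
with calibrated uncertainty, the pipeline round-trips), not field
performance on real fruit.

## Numerical choices and degenerate inputs

* **Savitzky–Golay**: half-window 10, polynomial order 2 (the published
  half-window; the order is the standard default, config-exposed).
  Derivatives are single-pass S–G derivatives with the same window,
  scaled by the signed grid spacing (the grid descends, −8 cm⁻¹/step) so
  units are per cm⁻¹. Edges are reflect-padded (mirror excluding the edge
  point) so outputs stay on the input grid and wavenumber bookkeeping
  survives pretreatment; a `shrink` policy is available. The kernel is
  built by solving the small window normal equations directly.
* **MSC**: reference = calibration-set mean (the standard convention);
  prediction-set spectra are always corrected against the
  calibration-set reference to avoid leakage. A constant reference or a
  regression slope below 1e-10 is an error, not a NaN. In the exact
  noise-free limit MSC's per-sample normalization leaves mild curvature
  in the absorbance–content relation (the correction divisor itself
  depends on the content), so noise-free tests assert exact
  interpolation only for the linearity-preserving methods.
* **Zero-order trajectories** are floored at 0 in the generator (a
  concentration cannot be negative) but the fitted line is *extrapolated*
  through zero for inversion. On the floored tail no inversion can
  recover the true day; the round-trip tests assert exact recovery on
  the linear regime and the line's root \(VCC_0/K\) on the floor.
* **Correlation with constant predictions** is undefined; it is reported
  as `NA` with an explicit flag instead of raising.
* **Rank-deficient MLR designs** are refused, naming the dependent
  columns. In a strictly noise-free study every wavenumber is exactly
  affine in the content, so any two selected wavenumbers are collinear —
  the noise-free pipeline checks use a single selected wavenumber for
  exactly this reason.
* **Region boundary** 9,091 cm⁻¹ is closed in both sub-regions as
  printed; on the default 8 cm⁻¹ grid it is off-grid, so no point is
  shared in practice.
* Whether region models re-run selection per region or subset a global
  selection is not documented in the source study; selection is re-run
  per region here (each region gets its own best wavenumbers).

## Problem sizes

The test-suite and acceptance workloads use the study design itself
(72 fruits, 2,052 spectra of 1,001 points — about a second to generate),
n = 200 observations per kinetic recovery dataset and 200 replicates for
the coverage study; the full suite runs in well under a minute.

## Known limitations

* The published per-table metric values (Rc/RMSEC on the original fruit)
  are not reproducible without the undeposited raw data; the harness
  computes the same statistics on synthetic studies instead.
* The SW-NIR region carries no planted vitamin C information in the
  default generator, mirroring its poor published performance, so models
  fitted there are expected to validate badly.
* Exponential-fit standard errors come from the local curvature at the
  optimum; for very small n they are approximate.
* The pipeline estimates shelf life in days under constant 20 °C storage;
  no Arrhenius/temperature extension is provided.
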