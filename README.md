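# jujubeNIR

Non-destructive vitamin C quantification in fresh jujube (*Ziziphus
jujuba*) from FT-NIR spectra, and shelf-life prediction from degradation
kinetics.

Vitamin C is the key quality index of fresh jujube and declines sharply
during room-temperature storage, but its reference assay
(2,6-dichloroindophenol titration) destroys the fruit. This package is for
chemometricians and postharvest researchers who want the complete pipeline
from absorbance spectra to shelf life:

* **Pretreatment** — Savitzky–Golay smoothing and derivatives,
  multiplicative scatter correction (MSC).
* **Calibration** — regression-coefficient (RC) wavelength selection and
  multiple linear regression of vitamin C content on a few selected
  absorbances, `VCC = b₀ + Σ bᵢXᵢ`, validated on a random 50/17 hold-out
  split with Rc/RMSEC and Rp/RMSEP.
* **Kinetics** — zero-order (`VCC = a + b·VCC₀ − Kt`) versus first-order
  (`VCC = C₀e^(−Kt)`) degradation models of the titrated contents against
  storage time, compared by correlation.
* **Shelf life** — algebraic inversion of the zero-order law for storage
  time from two spectra alone, and the safe storage time
  `t* = (a + b·VCC₀ − threshold)/K`.
* **Synthetic storage studies** — a generator reproducing the destructive
  longitudinal design (72 fruits in 18 groups, daily 3-position spectra,
  one group titrated per day over 18 days, scatter, noise, late-storage
  decay) with known ground truth, used throughout the tests.

## Worked example

```r
library(jujubeNIR)

study <- generate_study(study_config(seed = 1))
study
#> <study_dataset> 72 fruits in 18 groups, 2052 spectra, 72 titrations, 5 decayed

cal <- calibrate_study(study, method = "msc", region = "LWNIR", n_select = 5)
round(cal$metrics[, 1:5], 3)
#>   N    Rc RMSEC    Rp  RMSEP
#> 1 5 0.999 4.889 0.996 10.798

kin  <- kinetics_inputs(study, cal)
zero <- fit_zero_order(kin$vcc, kin$vcc0, kin$t)
zero
#> <zero_order_model> VCC = -30.597 +1.104*VCC0 -20.395*t

compare_kinetics(zero, fit_first_order(kin$vcc, kin$t),
                 kin$vcc, kin$vcc0, kin$t)
#>    form correlation         R     RMSEC
#> 1  zero      linear 0.9981924  6.697368
#> 2 first    exponent 0.9303262 41.280805
#> chosen form: zero-order

safe_storage_time(zero, vcc0 = 350)
#> [1] 17.4  # days until the modeled vitamin C pool is exhausted
```

The calibration recovers the spectral bands carrying vitamin C
information and predicts the titrated content with Rp ≈ 0.996 on held-out
fruits; the kinetic comparison correctly identifies the zero-order
(linear) decay the study was generated under, with a rate near the
generating 20.677 mg/100 g/day; and the fruit's vitamin C pool is
exhausted after about 17 days at 20 °C.

Published coefficient sets (the five-wavenumber LW-NIR calibration, the
zero- and first-order kinetic models and the literal printed storage-time
inversion) ship as `reference_models()` for comparison and regression
testing.

`run_pipeline(run_config(...))` executes all stages with one reproducible
configuration and writes model JSONs, metrics CSVs and a run log;
`inst/cli/jujube-nir.R` exposes `simulate`, `run-all` and `shelflife`
subcommands over the same functions.

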