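#' Published jujube vitamin C models
#'
#' The calibration and kinetic models reported for "Lizao" jujube stored at
#' room temperature (20 degC), transcribed at their printed precision. They
#' anchor the package's examples and regression tests and let the combined
#' shelf-life workflow be exercised without refitting:
#'
#' * `mlr`: the five-wavenumber LW-NIR calibration
#'   `VCC = 1409.098 + 1586.574*X1 + 2145.536*X2 - 3501.009*X3 -
#'   277.794*X4 + 30.116*X5` with X1..X5 the absorbances at 8,330, 6,900,
#'   5,666, 5,150 and 4,060 cm-1, and 95% CI of the mean prediction
#'   [173.683, 217.234].
#' * `zero`: the zero-order kinetic model
#'   `VCC = 338.787 + 0.044*VCC0 - 20.677*t`, 95% CI of the mean
#'   [150.648, 201.676].
#' * `first`: the first-order model `VCC = 550.58 * exp(-0.164*t)`.
#' * `inversion_as_printed`: the literal storage-time inversion
#'   `t = 17.128 - 0.002*VCC0 - 0.046*VCC` (see
#'   [invert_storage_time()] for why it differs from the algebraic inverse
#'   of `zero`).
#'
#' @return A list with elements `mlr`, `zero`, `first` and
#'   `inversion_as_printed`.
#' @examples
#' ref <- reference_models()
#' predict_vcc(ref$mlr, rep(0, 5)) # the intercept, 1409.098
#' @export
reference_models <- function() {
  list(
    mlr = mlr_model(
      intercept = 1409.098,
      coefficients = c("8330" = 1586.574, "6900" = 2145.536,
                       "5666" = -3501.009, "5150" = -277.794,
                       "4060" = 30.116),
      region = "LWNIR",
      ci_mean_low = 173.683, ci_mean_high = 217.234),
    zero = zero_order_model(a = 338.787, b = 0.044, K = 20.677,
                            ci_mean_low = 150.648, ci_mean_high = 201.676),
    first = first_order_model(C0 = 550.58, K = 0.164),
    inversion_as_printed = c(intercept = 17.128, vcc0 = -0.002,
                             vcc = -0.046)
  )
}
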