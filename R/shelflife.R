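#' Direct vitamin C prediction from day-0 spectra and storage time
#'
#' Composes the NIR calibration with the zero-order kinetic model: the
#' initial content is predicted from the day-0 absorbances, then propagated
#' through the linear decay,
#' \deqn{VCC(t) = a + b \cdot \widehat{VCC_0}(X) - K t.}
#'
#' @param mlr An [mlr_model()].
#' @param zero A [zero_order_model()].
#' @param day0_absorbances Absorbances at the model's selected wavenumbers
#'   on day 0 (vector, matrix or [nir_spectra]).
#' @param t Storage time(s), days, >= 0.
#' @return Predicted vitamin C content(s), mg/100 g.
#' @export
combined_predict <- function(mlr, zero, day0_absorbances, t) {
  stopifnot(inherits(mlr, "mlr_model"), inherits(zero, "zero_order_model"))
  if (any(t < 0)) stopf("storage time t must be >= 0")
  vcc0 <- predict_vcc(mlr, day0_absorbances)
  zero$a + zero$b * vcc0 - zero$K * t
}

#' Invert the zero-order model for storage time
#'
#' Two inversions are offered. `"algebraic"` solves the fitted line exactly,
#' \deqn{t = (a + b \cdot VCC_0 - VCC) / K,}
#' and round-trips with [predict_kinetic()] to machine precision.
#' `"as_printed"` evaluates the literal published inversion
#' `t = 17.128 - 0.002 VCC0 - 0.046 VCC`, whose rounded coefficients are
#' *not* the exact inverse of the published zero-order model (the sign of
#' the VCC0 term and the intercept disagree with the algebraic inverse);
#' it is provided for comparison against that report and ignores the fitted
#' `zero` parameters.
#'
#' @param zero A [zero_order_model()] (algebraic method; `K` must be
#'   non-zero).
#' @param vcc0 Initial content, mg/100 g.
#' @param vcc Current content, mg/100 g.
#' @param method `"algebraic"` or `"as_printed"`.
#' @return Estimated storage time, days (may be negative; see
#'   [shelf_life_from_spectra()]).
#' @export
invert_storage_time <- function(zero, vcc0, vcc,
                                method = c("algebraic", "as_printed")) {
  method <- match.arg(method)
  if (method == "as_printed") {
    return(17.128 - 0.002 * vcc0 - 0.046 * vcc)
  }
  stopifnot(inherits(zero, "zero_order_model"))
  if (zero$K == 0) {
    stopf("zero-order model with K = 0 is not invertible for storage time")
  }
  (zero$a + zero$b * vcc0 - vcc) / zero$K
}

#' Estimate storage time from two spectra
#'
#' The spectra-only shelf-life workflow: the initial content is predicted
#' from the day-0 absorbances, the current content from the day-t
#' absorbances (both through the same NIR calibration), and the storage
#' time is recovered by inverting the zero-order kinetic model. A negative
#' estimate (day-t spectra implying more vitamin C than day 0) is returned
#' as-is with `negative = TRUE` rather than clamped.
#'
#' @param mlr An [mlr_model()].
#' @param zero A [zero_order_model()].
#' @param day0_absorbances,dayt_absorbances Absorbances at the model's
#'   wavenumbers for the fresh and the stored measurement.
#' @param method Inversion method (see [invert_storage_time()]).
#' @return A list of class `shelf_life_prediction`: `t_est` (days),
#'   `method`, `vcc0_used`, `vcc_used` (mg/100 g) and `negative`.
#' @export
shelf_life_from_spectra <- function(mlr, zero, day0_absorbances,
                                    dayt_absorbances,
                                    method = c("algebraic", "as_printed")) {
  method <- match.arg(method)
  vcc0 <- predict_vcc(mlr, day0_absorbances)
  vcc <- predict_vcc(mlr, dayt_absorbances)
  if (length(vcc0) != length(vcc)) {
    stopf("day-0 and day-t inputs predict %d vs %d samples",
          length(vcc0), length(vcc))
  }
  t_est <- invert_storage_time(zero, vcc0, vcc, method)
  structure(list(t_est = t_est, method = method,
                 vcc0_used = vcc0, vcc_used = vcc,
                 negative = any(t_est < 0)),
            class = "shelf_life_prediction")
}

#' @export
print.shelf_life_prediction <- function(x, ...) {
  cat(sprintf("<shelf_life_prediction> t = %s days (%s inversion)\n",
              paste(round(x$t_est, 3), collapse = ", "), x$method))
  if (x$negative) {
    cat("  note: negative estimate(s); day-t spectra imply more vitamin C than day 0\n")
  }
  invisible(x)
}

#' Safe storage time until a vitamin C threshold
#'
#' The day on which the modeled content crosses `threshold`:
#' \deqn{t^* = (a + b \cdot VCC_0 - \mathrm{threshold}) / K.}
#' The default threshold of 0 mg/100 g treats exhaustion of vitamin C as
#' the end of shelf life; it is a modeling convention, not a food-safety
#' standard, and is therefore exposed.
#'
#' @param zero A [zero_order_model()] with `K > 0`.
#' @param vcc0 Initial content, mg/100 g.
#' @param threshold End-of-life content, mg/100 g.
#' @return Safe storage time, days.
#' @export
safe_storage_time <- function(zero, vcc0, threshold = 0) {
  stopifnot(inherits(zero, "zero_order_model"))
  if (zero$K <= 0) {
    stopf("non-degrading model (K <= 0): safe storage time is unbounded")
  }
  (zero$a + zero$b * vcc0 - threshold) / zero$K
}
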