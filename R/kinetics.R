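#' Zero-order degradation model
#'
#' Linear decline of vitamin C with storage time,
#' \deqn{VCC = a + b \cdot VCC_0 - K t,}
#' a three-parameter regression on the predicted initial content and the
#' storage time. The textbook zero-order law \eqn{C = C_0 - K t} is the
#' special case `a = 0, b = 1` (see `textbook` in [fit_zero_order()]).
#'
#' @param a Intercept, mg/100 g.
#' @param b Coefficient on the initial content (dimensionless).
#' @param K Degradation rate, mg/100 g per day. A warning is issued when
#'   `K <= 0` (a non-degrading fit).
#' @param ci_mean_low,ci_mean_high Optional 95% CI of the mean fitted value.
#' @param n Number of observations used, optional.
#' @return A list of class `zero_order_model`.
#' @export
zero_order_model <- function(a, b, K, ci_mean_low = NA_real_,
                             ci_mean_high = NA_real_, n = NA_integer_) {
  check_number(a, "a")
  check_number(b, "b")
  check_number(K, "K")
  if (K <= 0) {
    warning("zero-order rate K is not positive: the fit does not degrade",
            call. = FALSE)
  }
  structure(list(a = a, b = b, K = K, ci_mean_low = ci_mean_low,
                 ci_mean_high = ci_mean_high, n = n),
            class = "zero_order_model")
}

#' @export
print.zero_order_model <- function(x, ...) {
  cat(sprintf("<zero_order_model> VCC = %.3f %+.3f*VCC0 %+.3f*t\n",
              x$a, x$b, -x$K))
  invisible(x)
}

#' First-order degradation model
#'
#' Exponential decline \eqn{VCC = C_0 e^{-K t}}.
#'
#' @param C0 Initial content, mg/100 g (> 0; `NA` allowed as a placeholder
#'   for form-only comparisons).
#' @param K Rate constant, 1/day.
#' @param converged Convergence flag from the nonlinear fit.
#' @param n Number of observations used, optional.
#' @return A list of class `first_order_model`.
#' @export
first_order_model <- function(C0, K, converged = NA, n = NA_integer_) {
  if (!is.na(C0)) {
    check_number(C0, "C0", lower = .Machine$double.eps)
  }
  check_number(K, "K")
  structure(list(C0 = C0, K = K, converged = converged, n = n),
            class = "first_order_model")
}

#' @export
print.first_order_model <- function(x, ...) {
  cat(sprintf("<first_order_model> VCC = %.3f * exp(%+.4f*t)\n", x$C0, -x$K))
  invisible(x)
}

#' Fit the zero-order kinetic model by ordinary least squares
#'
#' Regresses the measured content on the initial content and storage time,
#' `vcc ~ vcc0 + t`; the rate `K` is the negated time coefficient. With
#' `textbook = TRUE` the classical two-parameter law is fitted instead
#' (`a = 0`, `b = 1` fixed, so `vcc - vcc0` is regressed on `t` without
#' intercept).
#'
#' @param vcc Measured vitamin C contents (mg/100 g).
#' @param vcc0 Initial contents (mg/100 g), typically predicted from day-1
#'   spectra by the NIR model.
#' @param t Storage times (days).
#' @param textbook Fit the two-parameter special case.
#' @return A [zero_order_model()] with the 95% CI of the mean fitted value
#'   and, as attribute `"fit"`, the underlying `lm` object.
#' @export
fit_zero_order <- function(vcc, vcc0, t, textbook = FALSE) {
  stopifnot(length(vcc) == length(vcc0), length(vcc) == length(t))
  if (length(vcc) < 4L) stopf("need at least 4 observations")
  if (stats::sd(t) == 0) stopf("storage times are all equal; K is not identifiable")
  if (textbook) {
    fit <- stats::lm(I(vcc - vcc0) ~ t - 1)
    K <- -unname(stats::coef(fit)[["t"]])
    model <- zero_order_model(a = 0, b = 1, K = K, n = length(vcc))
  } else {
    if (stats::sd(vcc0) > 0 &&
        abs(stats::cor(vcc0, t)) > 1 - 1e-10) {
      stopf("collinearity error: vcc0 and t are linearly dependent")
    }
    fit <- stats::lm(vcc ~ vcc0 + t)
    cf <- stats::coef(fit)
    n <- length(vcc)
    # computed directly so exact (zero-residual) data stay warning-free
    sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
    half <- stats::qt(0.975, fit$df.residual) * sigma / sqrt(n)
    model <- zero_order_model(a = unname(cf[["(Intercept)"]]),
                              b = unname(cf[["vcc0"]]),
                              K = -unname(cf[["t"]]),
                              ci_mean_low = mean(stats::fitted(fit)) - half,
                              ci_mean_high = mean(stats::fitted(fit)) + half,
                              n = n)
  }
  attr(model, "fit") <- fit
  model
}

#' Fit the first-order kinetic model by nonlinear least squares
#'
#' Fits \eqn{C_0 e^{-K t}} by Levenberg-Marquardt nonlinear least squares,
#' initialized from a log-linear regression on the strictly positive
#' responses (log-linearization is used only to start the optimizer, not as
#' the estimator, to avoid its bias under additive noise).
#'
#' @param vcc Measured contents (mg/100 g); at least one must be positive.
#' @param t Storage times (days).
#' @return A [first_order_model()] with a `converged` flag and, as
#'   attribute `"fit"`, the `nls` object (when the optimizer ran).
#' @export
fit_first_order <- function(vcc, t) {
  stopifnot(length(vcc) == length(t))
  if (length(vcc) < 3L) stopf("need at least 3 observations")
  pos <- vcc > 0
  if (!any(pos)) stopf("invalid data: all responses are <= 0; cannot fit an exponential")
  init <- stats::lm(log(vcc[pos]) ~ t[pos])
  C0_0 <- exp(unname(stats::coef(init)[1]))
  K_0 <- -unname(stats::coef(init)[2])
  if (!is.finite(K_0)) K_0 <- 0
  # perfect exponential data: the initializer already interpolates
  if (all(pos) && max(abs(vcc - C0_0 * exp(-K_0 * t))) <
        1e-9 * max(abs(vcc))) {
    return(first_order_model(C0 = C0_0, K = K_0, converged = TRUE,
                             n = length(vcc)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(vcc ~ C0 * exp(-K * t),
                      data = data.frame(vcc = vcc, t = t),
                      start = list(C0 = max(C0_0, 1e-6), K = K_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stopf("first-order fit failed to converge: %s", conditionMessage(e))
    })
  cf <- stats::coef(fit)
  info <- fit$convInfo
  model <- first_order_model(C0 = unname(cf[["C0"]]), K = unname(cf[["K"]]),
                             converged = isTRUE(info$isConv),
                             n = length(vcc))
  attr(model, "fit") <- fit
  model
}

#' Evaluate a kinetic model
#'
#' Evaluates the closed form of a fitted kinetic model at given inputs.
#' The zero-order prediction is the linear extrapolation `a + b*vcc0 - K*t`
#' and is deliberately not floored at zero: shelf-life estimation inverts
#' this line through its zero crossing.
#'
#' @param model A [zero_order_model()] or [first_order_model()].
#' @param vcc0 Initial content (mg/100 g); ignored by the first-order form,
#'   which carries its own fitted `C0`.
#' @param t Storage times (days), >= 0.
#' @return Predicted vitamin C contents.
#' @export
predict_kinetic <- function(model, vcc0 = NA_real_, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stopf("storage time t must be >= 0")
  if (inherits(model, "zero_order_model")) {
    model$a + model$b * vcc0 - model$K * t
  } else if (inherits(model, "first_order_model")) {
    model$C0 * exp(-model$K * t)
  } else {
    stopf("`model` must be a zero_order_model or first_order_model")
  }
}

#' Compare zero-order and first-order fits
#'
#' Computes, for each model, the Pearson correlation and RMSE between
#' observed and fitted contents on the same observations, and chooses the
#' form with the larger correlation (ties go to zero order, the simpler
#' linear form).
#'
#' @param zero A [zero_order_model()].
#' @param first A [first_order_model()].
#' @param vcc,vcc0,t The shared observations both models were fitted on.
#' @return A list of class `kinetics_comparison`: `table` (one row per
#'   form: `form`, `correlation`, `R`, `RMSEC`), `chosen` (`"zero"` or
#'   `"first"`) and `chosen_model`.
#' @export
compare_kinetics <- function(zero, first, vcc, vcc0, t) {
  stopifnot(inherits(zero, "zero_order_model"),
            inherits(first, "first_order_model"))
  pred_z <- predict_kinetic(zero, vcc0, t)
  pred_f <- predict_kinetic(first, t = t)
  tab <- data.frame(
    form = c("zero", "first"),
    correlation = c("linear", "exponent"),
    R = c(as.numeric(safe_cor(vcc, pred_z)),
          as.numeric(safe_cor(vcc, pred_f))),
    RMSEC = c(rmse(vcc, pred_z), rmse(vcc, pred_f)))
  chosen <- if (!is.na(tab$R[2]) && !is.na(tab$R[1]) &&
                tab$R[2] > tab$R[1]) "first" else "zero"
  structure(list(table = tab, chosen = chosen,
                 chosen_model = if (chosen == "zero") zero else first),
            class = "kinetics_comparison")
}

#' @export
print.kinetics_comparison <- function(x, ...) {
  print(x$table)
  cat(sprintf("chosen form: %s-order\n", x$chosen))
  invisible(x)
}
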