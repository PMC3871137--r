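#' Serialize fitted models to JSON
#'
#' Writes a model with a `form` tag so files are self-describing:
#' `"mlr"`, `"zero_order"` or `"first_order"`. [read_model()] restores the
#' corresponding S3 object.
#'
#' @param model An [mlr_model()], [zero_order_model()] or
#'   [first_order_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "mlr_model")) {
    list(form = "mlr", intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         selected_wavenumbers = model$selected_wavenumbers,
         region = if (is.null(model$region)) NULL else model$region$name,
         pretreatment = model$pretreatment,
         ci_mean_low = model$ci_mean_low, ci_mean_high = model$ci_mean_high,
         n = model$n)
  } else if (inherits(model, "zero_order_model")) {
    list(form = "zero_order", a = model$a, b = model$b, K = model$K,
         ci_mean_low = model$ci_mean_low, ci_mean_high = model$ci_mean_high,
         n = model$n)
  } else if (inherits(model, "first_order_model")) {
    list(form = "first_order", C0 = model$C0, K = model$K,
         converged = model$converged, n = model$n)
  } else {
    stopf("cannot serialize an object of class '%s'", class(model)[1])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()`: the restored model object.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  na_or <- function(v) if (is.null(v)) NA_real_ else v
  switch(x$form,
    mlr = mlr_model(
      intercept = x$intercept,
      coefficients = unlist(x$coefficients),
      region = x$region, pretreatment = x$pretreatment,
      ci_mean_low = na_or(x$ci_mean_low),
      ci_mean_high = na_or(x$ci_mean_high),
      n = if (is.null(x$n)) NA_integer_ else x$n),
    zero_order = zero_order_model(
      a = x$a, b = x$b, K = x$K,
      ci_mean_low = na_or(x$ci_mean_low),
      ci_mean_high = na_or(x$ci_mean_high),
      n = if (is.null(x$n)) NA_integer_ else x$n),
    first_order = first_order_model(
      C0 = na_or(x$C0), K = x$K,
      converged = if (is.null(x$converged)) NA else x$converged,
      n = if (is.null(x$n)) NA_integer_ else x$n),
    stopf("'%s' has unknown model form '%s'", path, x$form))
}
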