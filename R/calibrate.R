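#' Calibration / prediction split specification
#'
#' The hold-out design used for model validation: decayed fruits are
#' excluded first, then `n_calibration` fruits are drawn uniformly at random
#' for the calibration set and `n_prediction` of the remainder for the
#' prediction set. The defaults (50/17 of 67 usable fruits after 5 decayed
#' are removed) mirror the storage study's split.
#'
#' @param n_calibration,n_prediction Set sizes.
#' @param exclude_decayed Drop fruits flagged as decayed before splitting.
#' @param seed Integer seed for the random draw.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(n_calibration = 50, n_prediction = 17,
                       exclude_decayed = TRUE, seed = 1L) {
  structure(list(n_calibration = check_count(n_calibration, "n_calibration"),
                 n_prediction = check_count(n_prediction, "n_prediction"),
                 exclude_decayed = isTRUE(exclude_decayed),
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "split_spec")
}

#' Split study fruits into calibration and prediction sets
#'
#' @param study A `study_dataset`.
#' @param spec A [split_spec()].
#' @return A list with character vectors `calibration` and `prediction` of
#'   fruit ids (disjoint).
#' @export
split_samples <- function(study, spec = split_spec()) {
  stopifnot(inherits(study, "study_dataset"), inherits(spec, "split_spec"))
  candidates <- study$manifest$fruit
  if (spec$exclude_decayed) {
    candidates <- candidates[!study$manifest$decayed]
  }
  need <- spec$n_calibration + spec$n_prediction
  if (need > length(candidates)) {
    stopf("split error: need %d + %d fruits but only %d are available",
          spec$n_calibration, spec$n_prediction, length(candidates))
  }
  with_local_seed(spec$seed, {
    cal <- sample(candidates, spec$n_calibration)
    pred <- sample(setdiff(candidates, cal), spec$n_prediction)
    list(calibration = sort(cal), prediction = sort(pred))
  })
}

#' Titration-day spectra and reference values
#'
#' Builds the supervised calibration table of a study: for each fruit, the
#' replicate-averaged spectrum measured on its titration day paired with the
#' titrated vitamin C content.
#'
#' @param study A `study_dataset`.
#' @return A list with `spectra` (one averaged spectrum per fruit, in
#'   manifest order) and `vcc` (measured mg/100 g, same order).
#' @export
titration_day_spectra <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  avg <- average_replicates(study$spectra)
  key <- paste(study$titrations$fruit, study$titrations$day)
  idx <- match(key, paste(avg$meta$fruit, avg$meta$day))
  if (anyNA(idx)) {
    stopf("no spectra found for titration of fruit %s",
          study$titrations$fruit[which(is.na(idx))[1]])
  }
  list(spectra = avg[idx], vcc = study$titrations$vcc_measured)
}

#' Regression-coefficient wavelength selection
#'
#' Computes a full-spectrum regression-coefficient (RC) vector by
#' ridge-stabilized least squares on centered data (penalty
#' `lambda = 1e-3 * trace(X'X) / p` by default, needed because the spectral
#' design has far more wavenumbers than samples), locates the local maxima
#' of |RC| along the wavenumber axis, and returns the `n_select` maxima with
#' the largest |RC|. Ties in |RC| are broken toward the lower wavenumber.
#'
#' @param X Sample-by-wavenumber absorbance matrix, or an [nir_spectra].
#' @param y Reference vitamin C contents (mg/100 g).
#' @param n_select Number of wavenumbers to return.
#' @param wavenumbers Wavenumber per column of `X` (taken from the
#'   [nir_spectra] when one is given), descending.
#' @param lambda Ridge penalty; `NULL` for the trace-scaled default.
#' @return Selected wavenumbers, sorted descending.
#' @export
select_wavenumbers_rc <- function(X, y, n_select, wavenumbers = NULL,
                                  lambda = NULL) {
  if (inherits(X, "nir_spectra")) {
    wavenumbers <- X$wavenumbers
    X <- X$values
  }
  n_select <- check_count(n_select, "n_select")
  stopifnot(is.matrix(X), length(y) == nrow(X),
            length(wavenumbers) == ncol(X))
  rc <- rc_vector(X, y, lambda)
  peaks <- local_maxima(abs(rc))
  if (length(peaks) < n_select) {
    stopf("selection error: only %d local |RC| maxima exist, %d requested",
          length(peaks), n_select)
  }
  # rank by |RC| descending; ties go to the lower wavenumber
  ord <- peaks[order(-abs(rc[peaks]), wavenumbers[peaks])]
  sel <- ord[seq_len(n_select)]
  sort(wavenumbers[sel], decreasing = TRUE)
}

rc_vector <- function(X, y, lambda = NULL) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  if (is.null(lambda)) lambda <- 1e-3 * sum(diag(XtX)) / ncol(X)
  if (lambda <= 0) lambda <- .Machine$double.eps
  drop(solve(XtX + diag(lambda, ncol(X)), crossprod(Xc, yc)))
}

# Indices of local maxima of a non-negative profile; endpoints qualify
# against their single neighbour; a flat plateau contributes its boundary
# points (duplicates are then resolved by the selection tie-break).
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which((v >= left & v > right) | (v > left & v >= right))
}

#' Multiple linear regression calibration model
#'
#' Ordinary least-squares regression of vitamin C content on the absorbances
#' at a few selected wavenumbers,
#' \deqn{VCC = b_0 + b_1 X_1 + \dots + b_p X_p,}
#' the standard MLR form of NIR calibration. `ci_mean_low` / `ci_mean_high`
#' bound the mean fitted value at 95% confidence (t-based,
#' \eqn{\bar{y} \pm t_{0.975, n-p-1} s / \sqrt{n}}).
#'
#' `mlr_model()` constructs a model from known coefficients (e.g. a
#' published calibration); [fit_mlr()] estimates one from data.
#'
#' @param intercept Intercept, mg/100 g.
#' @param coefficients Named numeric vector, one coefficient per selected
#'   wavenumber; names are the wavenumbers in cm-1.
#' @param region Spectral region the model applies to (name or
#'   [spectral_region()]), optional.
#' @param pretreatment Pretreatment method name the model expects, optional.
#' @param ci_mean_low,ci_mean_high Optional 95% CI bounds of the mean
#'   prediction.
#' @param n Calibration-set size, optional.
#' @return A list of class `mlr_model`.
#' @export
mlr_model <- function(intercept, coefficients, region = NULL,
                      pretreatment = NULL, ci_mean_low = NA_real_,
                      ci_mean_high = NA_real_, n = NA_integer_) {
  check_number(intercept, "intercept")
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            !is.null(names(coefficients)))
  wn <- as.numeric(names(coefficients))
  if (anyNA(wn)) stopf("coefficient names must be wavenumbers in cm-1")
  if (is.character(region)) region <- spectral_region(region)
  structure(list(intercept = intercept, coefficients = coefficients,
                 selected_wavenumbers = wn, region = region,
                 pretreatment = pretreatment,
                 ci_mean_low = ci_mean_low, ci_mean_high = ci_mean_high,
                 n = n),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model> VCC = %.3f %s\n", x$intercept,
              paste(sprintf("%+.3f*A(%g)", x$coefficients,
                            x$selected_wavenumbers), collapse = " ")))
  if (!is.na(x$ci_mean_low)) {
    cat(sprintf("  95%% CI of mean prediction: [%.3f, %.3f]\n",
                x$ci_mean_low, x$ci_mean_high))
  }
  invisible(x)
}

#' Fit an MLR calibration by ordinary least squares
#'
#' @param X Matrix of absorbances at the selected wavenumbers (samples in
#'   rows), or an [nir_spectra] already restricted to them.
#' @param y Reference vitamin C contents (mg/100 g).
#' @param wavenumbers Wavenumber per column of `X`.
#' @param region,pretreatment Metadata stored on the model.
#' @return An [mlr_model()] with the 95% CI of the mean fitted value.
#' @export
fit_mlr <- function(X, y, wavenumbers = NULL, region = NULL,
                    pretreatment = NULL) {
  if (inherits(X, "nir_spectra")) {
    wavenumbers <- X$wavenumbers
    X <- X$values
  }
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(wavenumbers) == ncol(X))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) {
    stopf("need more samples (%d) than coefficients plus intercept (%d)",
          n, p + 1L)
  }
  design <- cbind(1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- setdiff(seq_len(ncol(design)), qrd$pivot[seq_len(qrd$rank)]) - 1L
    stopf("collinearity error: absorbances at %s are linearly dependent",
          paste(wavenumbers[dep], collapse = ", "))
  }
  fit <- stats::lm.fit(design, y)
  coefs <- fit$coefficients
  df <- n - p - 1L
  sigma <- sqrt(sum(fit$residuals^2) / df)
  half <- stats::qt(0.975, df) * sigma / sqrt(n)
  fitted_mean <- mean(y - fit$residuals)
  mlr_model(intercept = unname(coefs[1]),
            coefficients = stats::setNames(coefs[-1], wavenumbers),
            region = region, pretreatment = pretreatment,
            ci_mean_low = fitted_mean - half,
            ci_mean_high = fitted_mean + half, n = n)
}

#' Predict vitamin C content from spectra
#'
#' Evaluates `intercept + sum(coefficients * absorbance)` per sample. The
#' input must carry absorbances at exactly the model's selected wavenumbers
#' (an [nir_spectra] is subset by matching its grid; a bare vector/matrix is
#' taken column-per-wavenumber in model order).
#'
#' @param model An [mlr_model()].
#' @param spectra An [nir_spectra], or a numeric vector / matrix of
#'   absorbances at the model's wavenumbers.
#' @return Predicted vitamin C contents, mg/100 g.
#' @export
predict_vcc <- function(model, spectra) {
  stopifnot(inherits(model, "mlr_model"))
  if (inherits(spectra, "nir_spectra")) {
    idx <- match(model$selected_wavenumbers, spectra$wavenumbers)
    if (anyNA(idx)) {
      stopf("grid mismatch: wavenumber %g cm-1 is not in the spectra",
            model$selected_wavenumbers[which(is.na(idx))[1]])
    }
    A <- spectra$values[, idx, drop = FALSE]
  } else {
    A <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1L)
    if (ncol(A) != length(model$coefficients)) {
      stopf("grid mismatch: model has %d wavenumbers but input has %d columns",
            length(model$coefficients), ncol(A))
    }
  }
  drop(model$intercept + A %*% model$coefficients)
}

#' @rdname predict_vcc
#' @param object,newdata,... Standard [stats::predict()] interface.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  predict_vcc(object, newdata)
}

#' Calibration and prediction metrics
#'
#' Computes the standard NIR validation statistics: Pearson correlation
#' between predicted and measured content in the calibration (`Rc`) and
#' prediction (`Rp`) sets, and root-mean-square errors `RMSEC` / `RMSEP`
#' (denominator n). `N` is the number of selected wavenumbers. Constant
#' predictions make the correlation undefined; this is reported as `NA`
#' with `r_undefined = TRUE` rather than an error.
#'
#' @param model An [mlr_model()].
#' @param calibration,prediction Lists with elements `spectra` (or a matrix
#'   of selected absorbances, element `X`) and `vcc`.
#' @return One-row `data.frame`: `N`, `Rc`, `RMSEC`, `Rp`, `RMSEP`,
#'   `r_undefined`.
#' @export
evaluate_calibration <- function(model, calibration, prediction) {
  eval_set <- function(set) {
    input <- if (!is.null(set$spectra)) set$spectra else set$X
    if (is.null(input) || is.null(set$vcc) || length(set$vcc) == 0L) {
      stopf("evaluation sets need non-empty `spectra` (or `X`) and `vcc`")
    }
    pred <- predict_vcc(model, input)
    list(r = safe_cor(set$vcc, pred), rmse = rmse(set$vcc, pred))
  }
  cal <- eval_set(calibration)
  pred <- eval_set(prediction)
  data.frame(N = length(model$coefficients),
             Rc = as.numeric(cal$r), RMSEC = cal$rmse,
             Rp = as.numeric(pred$r), RMSEP = pred$rmse,
             r_undefined = isTRUE(attr(cal$r, "undefined")) ||
               isTRUE(attr(pred$r, "undefined")))
}

#' Calibrate one region/pretreatment combination on a study
#'
#' The full single-model workflow: average replicates, take titration-day
#' spectra, pretreat (fitting any MSC reference on the calibration set
#' only), restrict to the region, select wavenumbers by RC on the
#' calibration set, fit the MLR and evaluate on both sets.
#'
#' @param study A `study_dataset`.
#' @param method Pretreatment name (see [pretreat()]).
#' @param region Region name or [spectral_region()].
#' @param n_select Number of wavenumbers to select.
#' @param split A [split_spec()] or the list returned by [split_samples()].
#' @param half_window,poly_order Savitzky-Golay settings.
#' @return A list with `model` ([mlr_model()]), `metrics` (one-row
#'   `data.frame`), `selected` wavenumbers and the `split` used.
#' @export
calibrate_study <- function(study, method = "msc", region = "LWNIR",
                            n_select = 5, split = split_spec(),
                            half_window = 10, poly_order = 2) {
  stopifnot(inherits(study, "study_dataset"))
  if (inherits(split, "split_spec")) split <- split_samples(study, split)
  tab <- titration_day_spectra(study)
  cal_i <- match(split$calibration, tab$spectra$meta$fruit)
  pred_i <- match(split$prediction, tab$spectra$meta$fruit)
  if (anyNA(cal_i) || anyNA(pred_i)) {
    stopf("split refers to fruits without titration-day spectra")
  }
  method <- normalize_method(method)
  cal_sp <- tab$spectra[cal_i]
  pred_sp <- tab$spectra[pred_i]
  ref <- NULL
  if (method == "msc") {
    ref <- msc_fit(cal_sp)
    cal_sp <- msc_apply(cal_sp, ref)
    pred_sp <- msc_apply(pred_sp, ref)
  } else {
    cal_sp <- pretreat(cal_sp, method, half_window, poly_order)
    pred_sp <- pretreat(pred_sp, method, half_window, poly_order)
  }
  cal_sp <- restrict_region(cal_sp, region)
  pred_sp <- restrict_region(pred_sp, region)
  y_cal <- tab$vcc[cal_i]
  y_pred <- tab$vcc[pred_i]
  selected <- select_wavenumbers_rc(cal_sp, y_cal, n_select)
  idx <- match(selected, cal_sp$wavenumbers)
  model <- fit_mlr(cal_sp$values[, idx, drop = FALSE], y_cal,
                   wavenumbers = selected, region = region,
                   pretreatment = method)
  metrics <- evaluate_calibration(
    model,
    list(X = cal_sp$values[, idx, drop = FALSE], vcc = y_cal),
    list(X = pred_sp$values[, idx, drop = FALSE], vcc = y_pred))
  list(model = model, metrics = metrics, selected = selected, split = split,
       msc_reference = ref,
       settings = list(method = method, region = region,
                       half_window = half_window, poly_order = poly_order))
}

#' Compare pretreatment techniques on one study
#'
#' Runs [calibrate_study()] once per pretreatment on the same split and
#' returns the metrics table (one row per method, in the order given).
#'
#' @inheritParams calibrate_study
#' @param methods Pretreatment names to compare.
#' @return `data.frame` with columns `method`, `N`, `Rc`, `RMSEC`, `Rp`,
#'   `RMSEP`.
#' @export
compare_pretreatments <- function(study,
                                  methods = c("raw", "sg", "msc", "d1", "d2"),
                                  region = "LWNIR", n_select = 5,
                                  split = split_spec(),
                                  half_window = 10, poly_order = 2) {
  if (inherits(split, "split_spec")) split <- split_samples(study, split)
  rows <- lapply(methods, function(m) {
    res <- calibrate_study(study, m, region, n_select, split,
                           half_window, poly_order)
    cbind(data.frame(method = m), res$metrics)
  })
  do.call(rbind, rows)
}
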