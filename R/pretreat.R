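#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filter over a window of
#' `2 * half_window + 1` grid points. With `deriv_order > 0` the filter
#' returns the smoothed derivative with respect to wavenumber, scaled by the
#' (signed) grid spacing so units are absorbance per cm-1 per order. The
#' default window of 10 points to each side matches common FT-NIR practice
#' for this instrument resolution.
#'
#' Edge handling: `"reflect"` mirrors the spectrum about its end points
#' (excluding the edge point itself) so the output stays on the input grid;
#' `"shrink"` drops the `half_window` points at each end.
#'
#' @param spectra An [nir_spectra] object or a numeric vector on `grid`.
#' @param half_window Points to each side of the window center (default 10).
#' @param poly_order Degree of the local polynomial (default 2); must
#'   satisfy `2 * half_window + 1 > poly_order >= deriv_order`.
#' @param deriv_order 0 (smooth), 1 or 2.
#' @param edge_policy `"reflect"` or `"shrink"`.
#' @param grid Required when `spectra` is a bare numeric vector and
#'   `deriv_order > 0`.
#' @return Same shape as the input (grid shortened under `"shrink"`).
#' @export
savgol <- function(spectra, half_window = 10, poly_order = 2,
                   deriv_order = 0, edge_policy = c("reflect", "shrink"),
                   grid = NULL) {
  edge_policy <- match.arg(edge_policy)
  half_window <- check_count(half_window, "half_window")
  poly_order <- check_count(poly_order, "poly_order", lower = 0L)
  deriv_order <- check_count(deriv_order, "deriv_order", lower = 0L)
  window <- 2L * half_window + 1L
  if (!(window > poly_order && poly_order >= deriv_order)) {
    stopf("need window (%d) > poly_order (%d) >= deriv_order (%d)",
          window, poly_order, deriv_order)
  }
  if (inherits(spectra, "nir_spectra")) {
    out <- savgol_matrix(spectra$values, spectra$wavenumbers, half_window,
                         poly_order, deriv_order, edge_policy)
    return(nir_spectra(out$values, out$wavenumbers, spectra$meta))
  }
  stopifnot(is.numeric(spectra))
  if (is.null(grid)) {
    if (deriv_order > 0L) {
      stopf("`grid` is required to scale derivatives of a bare vector")
    }
    grid <- seq(length(spectra), 1)  # unit spacing placeholder
  }
  out <- savgol_matrix(matrix(spectra, 1L), grid, half_window, poly_order,
                       deriv_order, edge_policy)
  drop(out$values)
}

# Central-point Savitzky-Golay kernel: least-squares fit of a degree-p
# polynomial over offsets -h..h, evaluated (or differentiated) at offset 0.
savgol_kernel <- function(half_window, poly_order, deriv_order) {
  j <- seq(-half_window, half_window)
  A <- outer(j, 0:poly_order, `^`)
  # row deriv_order+1 of (A'A)^{-1} A' gives the coefficient of x^m; the
  # m-th derivative at 0 is m! times it
  coef <- solve(crossprod(A), t(A))
  coef[deriv_order + 1L, ] * factorial(deriv_order)
}

savgol_matrix <- function(values, wavenumbers, half_window, poly_order,
                          deriv_order, edge_policy) {
  n <- ncol(values)
  h <- half_window
  if (n < 2L * h + 1L) {
    stopf("filter window (%d points) exceeds spectrum length (%d)",
          2L * h + 1L, n)
  }
  kern <- savgol_kernel(h, poly_order, deriv_order)
  dx <- wavenumbers[2] - wavenumbers[1]  # negative on a descending grid
  kern <- kern / dx^deriv_order
  pad <- switch(edge_policy,
    reflect = cbind(values[, (h + 1L):2, drop = FALSE], values,
                    values[, (n - 1L):(n - h), drop = FALSE]),
    shrink = values)
  m <- ncol(pad) - 2L * h
  out <- matrix(0, nrow(values), m)
  for (k in seq_along(kern)) {
    out <- out + kern[k] * pad[, k:(k + m - 1L), drop = FALSE]
  }
  keep <- if (edge_policy == "shrink") (h + 1L):(n - h) else seq_len(n)
  rownames(out) <- rownames(values)
  list(values = out, wavenumbers = wavenumbers[keep])
}

#' Fit a multiplicative scatter correction reference
#'
#' The MSC reference is the point-wise mean spectrum of the calibration set.
#' Prediction-set spectra must be corrected against the calibration-set
#' reference (never their own mean) to avoid information leakage.
#'
#' @param spectra An [nir_spectra] with at least 2 spectra.
#' @return Numeric reference spectrum (one value per grid point).
#' @export
msc_fit <- function(spectra) {
  stopifnot(inherits(spectra, "nir_spectra"))
  if (nrow(spectra$values) < 2L) {
    stopf("MSC needs at least 2 spectra to form a mean reference")
  }
  colMeans(spectra$values)
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference `r` by ordinary least
#' squares, `x ~ a + b * r`, and corrected to `(x - a) / b`. This removes
#' per-sample affine scatter exactly: `msc_apply(a + b * x, x) == x`.
#'
#' @param spectra An [nir_spectra] or numeric vector on the reference grid.
#' @param reference Reference spectrum from [msc_fit()].
#' @return Corrected spectra, same shape as the input.
#' @export
msc_apply <- function(spectra, reference) {
  vals <- if (inherits(spectra, "nir_spectra")) spectra$values
          else matrix(spectra, 1L)
  if (ncol(vals) != length(reference)) {
    stopf("spectra have %d points but the MSC reference has %d",
          ncol(vals), length(reference))
  }
  vr <- stats::var(reference)
  if (vr == 0) stopf("MSC reference is constant; cannot regress on it")
  rc <- reference - mean(reference)
  b <- drop(vals %*% rc - rowSums(vals) * mean(rc)) / ((length(rc) - 1) * vr)
  if (any(abs(b) < 1e-10)) {
    stopf("degenerate MSC fit: spectrum %d is uncorrelated with the reference",
          which(abs(b) < 1e-10)[1])
  }
  a <- rowMeans(vals) - b * mean(reference)
  out <- sweep(sweep(vals, 1, a, "-"), 1, b, "/")
  if (inherits(spectra, "nir_spectra")) {
    nir_spectra(out, spectra$wavenumbers, spectra$meta)
  } else {
    drop(out)
  }
}

#' Pretreatment configuration and dispatcher
#'
#' Applies one of the pretreatments compared in the calibration harness:
#' `"raw"` (identity), `"sg"` (Savitzky-Golay smoothing), `"msc"`
#' (multiplicative scatter correction), `"d1"` / `"d2"` (first / second
#' Savitzky-Golay derivative). Method names are accepted case-insensitively;
#' `"sg_smooth"`, `"deriv1"` and `"deriv2"` are synonyms.
#'
#' For `"msc"`, pass the calibration-set reference via `reference` when
#' correcting prediction spectra; with `reference = NULL` the mean of
#' `spectra` itself is used (appropriate only for the calibration set).
#'
#' @param spectra An [nir_spectra] object.
#' @param method Pretreatment name.
#' @param half_window,poly_order Savitzky-Golay settings (see [savgol()]).
#' @param reference Optional MSC reference spectrum.
#' @return Pretreated [nir_spectra].
#' @export
pretreat <- function(spectra, method = c("raw", "sg", "msc", "d1", "d2"),
                     half_window = 10, poly_order = 2, reference = NULL) {
  method <- normalize_method(method[1])
  switch(method,
    raw = spectra,
    sg = savgol(spectra, half_window, poly_order, deriv_order = 0),
    d1 = savgol(spectra, half_window, poly_order, deriv_order = 1),
    d2 = savgol(spectra, half_window, poly_order, deriv_order = 2),
    msc = msc_apply(spectra,
                    if (is.null(reference)) msc_fit(spectra) else reference))
}

normalize_method <- function(method) {
  key <- tolower(gsub("[-_ ]", "", method))
  switch(key,
    raw = "raw",
    sg = , sgsmooth = , smoothing = "sg",
    msc = "msc",
    d1 = , deriv1 = , `1der` = "d1",
    d2 = , deriv2 = , `2der` = "d2",
    stopf("unknown pretreatment '%s' (use raw, sg, msc, d1 or d2)", method))
}
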