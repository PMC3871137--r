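#' Wavenumber grid for FT-NIR spectra
#'
#' Builds the shared wavenumber axis on which all spectra in a study live.
#' The instrument convention is a descending grid: scans run from 12,000 down
#' to 4,000 cm-1 at a uniform 8 cm-1 interval, giving 1001 points.
#'
#' @param start First (highest) wavenumber in cm-1.
#' @param end Last (lowest) wavenumber in cm-1.
#' @param by Grid spacing in cm-1 (positive).
#' @return Numeric vector of wavenumbers, strictly descending, uniformly
#'   spaced, all positive.
#' @examples
#' g <- spectrum_grid()
#' length(g) # 1001
#' @export
spectrum_grid <- function(start = 12000, end = 4000, by = 8) {
  check_number(start, "start", lower = .Machine$double.eps)
  check_number(end, "end", lower = .Machine$double.eps)
  check_number(by, "by", lower = .Machine$double.eps)
  if (end >= start) stopf("grid must descend: end (%s) < start (%s)", end, start)
  wn <- seq(start, end, by = -by)
  validate_grid(wn)
  wn
}

# Grid invariants: strictly descending, uniform spacing, positive values.
validate_grid <- function(wn) {
  if (length(wn) < 2L) stopf("a wavenumber grid needs at least 2 points")
  if (any(!is.finite(wn)) || any(wn <= 0)) {
    stopf("wavenumbers must be finite and positive")
  }
  d <- diff(wn)
  if (any(d >= 0)) {
    stopf("wavenumber grid must be strictly descending (row %d breaks order)",
          which(d >= 0)[1] + 1L)
  }
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    bad <- which(abs(d - d[1]) > 1e-6 * abs(d[1]))[1] + 1L
    stopf("wavenumber grid spacing is not uniform (row %d: step %g after %g)",
          bad, -d[bad - 1L], -d[1])
  }
  invisible(wn)
}

#' Collection of NIR spectra on a shared grid
#'
#' Container used throughout the pipeline: a samples-by-wavenumbers
#' absorbance matrix plus per-spectrum identity (fruit, measurement day,
#' probe position). Labels follow the `fruit_dayD_posP` convention; replicate
#' averages drop the `_posP` suffix.
#'
#' @param values Numeric matrix, one row per spectrum, one column per
#'   wavenumber.
#' @param wavenumbers Descending uniform grid (see [spectrum_grid()]).
#' @param meta Optional `data.frame` with columns `fruit`, `day`, `position`
#'   (position may be `NA` for averaged spectra). Reconstructed from row
#'   labels when missing.
#' @return An object of class `nir_spectra`.
#' @export
nir_spectra <- function(values, wavenumbers, meta = NULL) {
  values <- as.matrix(values)
  validate_grid(wavenumbers)
  if (ncol(values) != length(wavenumbers)) {
    stopf("values has %d columns but the grid has %d points",
          ncol(values), length(wavenumbers))
  }
  if (any(!is.finite(values))) stopf("absorbance values must all be finite")
  if (is.null(meta)) {
    if (is.null(rownames(values))) {
      rownames(values) <- sprintf("S%03d_day1_pos1", seq_len(nrow(values)))
    }
    meta <- parse_spectrum_labels(rownames(values))
  } else {
    stopifnot(is.data.frame(meta), nrow(meta) == nrow(values),
              all(c("fruit", "day") %in% names(meta)))
    if (is.null(meta$position)) meta$position <- NA_integer_
    rownames(values) <- spectrum_labels(meta)
  }
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 values = values, meta = meta),
            class = "nir_spectra")
}

spectrum_labels <- function(meta) {
  ifelse(is.na(meta$position),
         sprintf("%s_day%d", meta$fruit, meta$day),
         sprintf("%s_day%d_pos%d", meta$fruit, meta$day, meta$position))
}

parse_spectrum_labels <- function(labels) {
  m <- regmatches(labels,
                  regexec("^(.+)_day([0-9]+)(?:_pos([0-9]+))?$", labels))
  bad <- which(lengths(m) == 0L)
  if (length(bad) > 0L) {
    stopf("cannot parse spectrum label '%s' (expected fruit_dayD[_posP])",
          labels[bad[1]])
  }
  data.frame(
    fruit = vapply(m, `[`, "", 2L),
    day = as.integer(vapply(m, `[`, "", 3L)),
    position = vapply(m, function(x) {
      if (x[4L] == "") NA_integer_ else as.integer(x[4L])
    }, 1L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.nir_spectra <- function(x, ...) {
  cat(sprintf("<nir_spectra> %d spectra x %d wavenumbers (%g to %g cm-1)\n",
              nrow(x$values), length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' @export
`[.nir_spectra` <- function(x, i, ...) {
  nir_spectra(x$values[i, , drop = FALSE], x$wavenumbers,
              x$meta[i, , drop = FALSE])
}

#' Write spectra to CSV
#'
#' The canonical on-disk dialect: first column `wavenumber`, one column per
#' spectrum headed by its `fruit_dayD_posP` label, one row per grid point in
#' descending wavenumber order.
#'
#' @param spectra An [nir_spectra] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "nir_spectra"))
  df <- data.frame(wavenumber = spectra$wavenumbers,
                   t(spectra$values), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra()]: parses the shared grid once from the first
#' column (validating descending uniform spacing) and the sample identities
#' from column headers. Round-trips bit-exactly on the decimal representation
#' written.
#'
#' @param path CSV path in the dialect written by [write_spectra()].
#' @return An [nir_spectra] object.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stopf("'%s' has no spectrum columns", path)
  if (names(df)[1] != "wavenumber") {
    stopf("first column of '%s' must be 'wavenumber', found '%s'",
          path, names(df)[1])
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      stopf("column '%s' of '%s' contains non-numeric cells",
            names(df)[j], path)
    }
    if (anyNA(df[[j]])) {
      stopf("column '%s' of '%s' has missing cells (row %d)",
            names(df)[j], path, which(is.na(df[[j]]))[1])
    }
  }
  wn <- df[[1]]
  validate_grid(wn)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  nir_spectra(vals, wn, parse_spectrum_labels(rownames(vals)))
}

#' Average replicate probe positions
#'
#' Each fruit is scanned at several probe positions per day; the positions
#' are averaged (arithmetic mean, point-wise) into one spectrum per
#' fruit-day before any modeling.
#'
#' @param spectra An [nir_spectra] object with position-level spectra.
#' @return An [nir_spectra] object with one spectrum per fruit-day
#'   (`position` set to `NA`), ordered by fruit then day.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "nir_spectra"))
  key <- paste(spectra$meta$fruit, spectra$meta$day, sep = "\r")
  idx <- split(seq_len(nrow(spectra$values)), key)
  # preserve first-appearance order of keys
  idx <- idx[unique(key)]
  vals <- t(vapply(idx, function(i) colMeans(spectra$values[i, , drop = FALSE]),
                   numeric(length(spectra$wavenumbers))))
  first <- vapply(idx, `[`, 1L, 1L)
  meta <- data.frame(fruit = spectra$meta$fruit[first],
                     day = spectra$meta$day[first],
                     position = NA_integer_,
                     stringsAsFactors = FALSE)
  nir_spectra(vals, spectra$wavenumbers, meta)
}

#' Named spectral regions
#'
#' The three analysis windows: the full visible/near-infrared range
#' `VNIR` (4,000-12,000 cm-1), the short-wave `SWNIR` (9,091-12,000 cm-1)
#' and the long-wave `LWNIR` (4,000-9,091 cm-1). Bounds are closed on both
#' sides; 9,091 cm-1 belongs to both sub-regions as printed, though it is
#' off-grid for the default 8 cm-1 axis so no point is shared in practice.
#'
#' @param name One of `"VNIR"`, `"SWNIR"`, `"LWNIR"` (case-insensitive).
#' @return A list with `name`, `lo`, `hi` (cm-1), class `spectral_region`.
#' @export
spectral_region <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(gsub("[-_ ]", "", name))
  bounds <- switch(key,
    VNIR = c(4000, 12000),
    SWNIR = c(9091, 12000),
    LWNIR = c(4000, 9091),
    stopf("unknown spectral region '%s' (use VNIR, SWNIR or LWNIR)", name))
  structure(list(name = key, lo = bounds[1], hi = bounds[2]),
            class = "spectral_region")
}

#' Restrict spectra to a spectral region
#'
#' Keeps the grid points with `lo <= wavenumber <= hi` (closed interval).
#'
#' @param spectra An [nir_spectra] object.
#' @param region A [spectral_region()] or a region name.
#' @return An [nir_spectra] object on the sub-grid.
#' @export
restrict_region <- function(spectra, region) {
  stopifnot(inherits(spectra, "nir_spectra"))
  if (is.character(region)) region <- spectral_region(region)
  stopifnot(inherits(region, "spectral_region"))
  keep <- spectra$wavenumbers >= region$lo & spectra$wavenumbers <= region$hi
  if (!any(keep)) {
    stopf("region %s [%g, %g] does not overlap the grid [%g, %g]",
          region$name, region$lo, region$hi,
          min(spectra$wavenumbers), max(spectra$wavenumbers))
  }
  nir_spectra(spectra$values[, keep, drop = FALSE],
              spectra$wavenumbers[keep], spectra$meta)
}
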