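#' Write a study dataset to a directory
#'
#' One directory per study: `spectra.csv` (wavenumber column plus one column
#' per fruit-day-position), `manifest.csv`, `titrations.csv`, `truth.csv`
#' and `config.json`.
#'
#' @param study A `study_dataset` (see [generate_study()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra(study$spectra, file.path(dir, "spectra.csv"))
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(study$titrations, file.path(dir, "titrations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study dataset from a directory
#'
#' Inverse of [write_study()]. `truth.csv` and `config.json` are optional
#' (real studies have neither).
#'
#' @param dir Study directory.
#' @return A `study_dataset`.
#' @export
read_study <- function(dir) {
  need <- file.path(dir, c("spectra.csv", "manifest.csv", "titrations.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stopf("study directory '%s' is missing %s", dir,
          paste(basename(missing), collapse = ", "))
  }
  spectra <- read_spectra(file.path(dir, "spectra.csv"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  titrations <- utils::read.csv(file.path(dir, "titrations.csv"),
                                stringsAsFactors = FALSE)
  truth <- if (file.exists(file.path(dir, "truth.csv"))) {
    utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  } else NULL
  config <- if (file.exists(file.path(dir, "config.json"))) {
    cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                               simplifyVector = TRUE)
    do.call(study_config, cfg)
  } else NULL
  structure(list(grid = spectra$wavenumbers, spectra = spectra,
                 manifest = manifest, titrations = titrations,
                 truth = truth, config = config),
            class = "study_dataset")
}
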