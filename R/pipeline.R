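#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis so a run is fully
#' reproducible from one object: the study source (a directory written by
#' [write_study()], or a [study_config()] to simulate), the pretreatment,
#' region and wavelength count of the calibration, the hold-out split, the
#' shelf-life inversion method and the output directory. Validation happens
#' here, before any computation.
#'
#' @param study_dir Directory of an existing study, or `NULL` to simulate.
#' @param synth A [study_config()] used when `study_dir` is `NULL`.
#' @param method Pretreatment for the final calibration (see [pretreat()]).
#' @param methods Pretreatments compared in the harness table.
#' @param region Spectral region name.
#' @param n_select Number of wavenumbers the RC selection keeps.
#' @param split A [split_spec()].
#' @param shelf_method `"algebraic"` or `"as_printed"`.
#' @param out_dir Output directory for all artifacts.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(study_dir = NULL, synth = study_config(),
                       method = "msc",
                       methods = c("raw", "sg", "msc", "d1", "d2"),
                       region = "LWNIR", n_select = 5,
                       split = split_spec(),
                       shelf_method = c("algebraic", "as_printed"),
                       out_dir = tempfile("jujube_run_")) {
  if (!is.null(study_dir) && !dir.exists(study_dir)) {
    stopf("validation error: study directory '%s' does not exist", study_dir)
  }
  stopifnot(inherits(synth, "study_config"), inherits(split, "split_spec"))
  structure(list(study_dir = study_dir, synth = synth,
                 method = normalize_method(method),
                 methods = vapply(methods, normalize_method, ""),
                 region = spectral_region(region),
                 n_select = check_count(n_select, "n_select"),
                 split = split,
                 shelf_method = match.arg(shelf_method),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load) the study, average replicate
#' positions, pretreat, restrict the spectral region, split, select
#' wavenumbers, fit and evaluate the MLR calibration (for every compared
#' pretreatment), predict each fruit's initial vitamin C content from its
#' day-1 spectrum, fit and compare the zero- and first-order kinetic
#' models, and produce per-fruit shelf-life estimates for the prediction
#' set. All prediction-set processing uses only calibration-derived
#' artifacts (MSC reference, selection, coefficients). Re-running with an
#' identical configuration reproduces the artifacts bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the artifact `manifest` (file paths), the
#'   fitted `mlr` and kinetic models, the `comparison` and the metrics
#'   tables.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(path) {
    artifacts[[length(artifacts) + 1L]] <<- path
    path
  }

  study <- if (is.null(config$study_dir)) {
    st <- generate_study(config$synth)
    write_study(st, file.path(out, "study"))
    emit(file.path(out, "study"))
    st
  } else {
    read_study(config$study_dir)
  }

  split <- split_samples(study, config$split)
  ptab <- compare_pretreatments(study, config$methods, config$region,
                                config$n_select, split)
  utils::write.csv(ptab, emit(file.path(out, "metrics_pretreatments.csv")),
                   row.names = FALSE)

  cal <- calibrate_study(study, config$method, config$region,
                         config$n_select, split)
  write_model(cal$model, emit(file.path(out, "model_mlr.json")))
  utils::write.csv(cal$metrics, emit(file.path(out, "metrics_mlr.csv")),
                   row.names = FALSE)

  kin <- kinetics_inputs(study, cal)
  zero <- fit_zero_order(kin$vcc, kin$vcc0, kin$t)
  first <- fit_first_order(kin$vcc, kin$t)
  comp <- compare_kinetics(zero, first, kin$vcc, kin$vcc0, kin$t)
  write_model(zero, emit(file.path(out, "model_zero_order.json")))
  write_model(first, emit(file.path(out, "model_first_order.json")))
  utils::write.csv(comp$table, emit(file.path(out, "kinetics_comparison.csv")),
                   row.names = FALSE)

  shelf <- shelf_life_table(study, cal, zero, config$shelf_method)
  utils::write.csv(shelf, emit(file.path(out, "shelf_life.csv")),
                   row.names = FALSE)

  log <- list(config = list(method = config$method,
                            region = config$region$name,
                            n_select = config$n_select,
                            split_seed = config$split$seed,
                            synth_seed = if (is.null(config$study_dir))
                              config$synth$seed else NULL,
                            shelf_method = config$shelf_method),
              split = split,
              chosen_kinetic_form = comp$chosen,
              artifacts = basename(unlist(artifacts)))
  jsonlite::write_json(log, emit(file.path(out, "run_log.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = unlist(artifacts), study = study, split = split,
                 pretreatments = ptab, mlr = cal$model, zero = zero,
                 first = first, comparison = comp, shelf_life = shelf))
}

#' Kinetic-model inputs from a study and a fitted calibration
#'
#' For every non-decayed titrated fruit: the measured content, the storage
#' time `t = titration day - 1`, and the initial content predicted by the
#' NIR model from the fruit's day-1 spectrum (pretreated with the
#' calibration's method and, for MSC, its calibration-set reference).
#'
#' @param study A `study_dataset`.
#' @param calibration The list returned by [calibrate_study()].
#' @return `data.frame` with columns `fruit`, `t`, `vcc`, `vcc0`.
#' @export
kinetics_inputs <- function(study, calibration) {
  stopifnot(inherits(study, "study_dataset"))
  avg <- average_replicates(study$spectra)
  day1 <- avg[avg$meta$day == 1L]
  s <- calibration$settings
  day1 <- if (s$method == "msc") {
    msc_apply(day1, calibration$msc_reference)
  } else {
    pretreat(day1, s$method, s$half_window, s$poly_order)
  }
  day1 <- restrict_region(day1, s$region)
  keep <- !study$manifest$decayed
  fruits <- study$manifest$fruit[keep]
  i1 <- match(fruits, day1$meta$fruit)
  it <- match(fruits, study$titrations$fruit)
  data.frame(fruit = fruits,
             t = study$titrations$day[it] - 1,
             vcc = study$titrations$vcc_measured[it],
             vcc0 = predict_vcc(calibration$model, day1[i1]),
             stringsAsFactors = FALSE)
}

# Per-fruit shelf-life report for the prediction set: storage time
# re-estimated from the day-1 and titration-day spectra alone, plus the
# safe storage time implied by the fruit's predicted initial content.
shelf_life_table <- function(study, calibration, zero, method) {
  avg <- average_replicates(study$spectra)
  s <- calibration$settings
  prep <- function(sp) {
    sp <- if (s$method == "msc") msc_apply(sp, calibration$msc_reference)
          else pretreat(sp, s$method, s$half_window, s$poly_order)
    restrict_region(sp, s$region)
  }
  all_prep <- prep(avg)
  rows <- lapply(calibration$split$prediction, function(f) {
    tday <- study$titrations$day[study$titrations$fruit == f]
    i0 <- which(all_prep$meta$fruit == f & all_prep$meta$day == 1L)
    it <- which(all_prep$meta$fruit == f & all_prep$meta$day == tday)
    pred <- shelf_life_from_spectra(calibration$model, zero,
                                    all_prep[i0], all_prep[it], method)
    data.frame(fruit = f, true_t = tday - 1, t_est = pred$t_est,
               vcc0_pred = pred$vcc0_used, vcc_pred = pred$vcc_used,
               safe_storage_days = safe_storage_time(zero, pred$vcc0_used),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
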