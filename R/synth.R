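#' Titration record (2,6-dichloroindophenol assay)
#'
#' Bookkeeping for one destructive vitamin C determination. The dye titer
#' `T`, dilution multiple `A` and sample weight `W` convert the consumed dye
#' volume into a concentration via
#' \deqn{VCC = (V - V_0) \cdot T \cdot A / W \times 100}
#' in mg per 100 g fresh weight.
#'
#' @param V Dye volume consumed titrating the sample (mL).
#' @param V0 Dye volume consumed titrating the blank (mL).
#' @param T Dye titer (mg ascorbic acid per mL dye).
#' @param A Dilution multiple (>= 1).
#' @param W Sample weight (g).
#' @return A list of class `titration_record`.
#' @export
titration_record <- function(V, V0, T, A, W) {
  check_number(V, "V", lower = 0)
  check_number(V0, "V0", lower = 0)
  check_number(T, "T")
  check_number(A, "A")
  check_number(W, "W")
  if (W <= 0) stopf("invalid titration record: sample weight W must be > 0")
  if (T <= 0) stopf("invalid titration record: titer T must be > 0")
  if (A < 1) stopf("invalid titration record: dilution A must be >= 1")
  if (V < V0) stopf("invalid titration record: sample volume V (%g) < blank V0 (%g)",
                    V, V0)
  structure(list(V = V, V0 = V0, T = T, A = A, W = W),
            class = "titration_record")
}

#' Vitamin C concentration from a titration record
#'
#' @param rec A [titration_record()].
#' @return Vitamin C concentration in mg/100 g (non-negative).
#' @examples
#' titration_vcc(titration_record(V = 5, V0 = 0.1, T = 0.2, A = 10, W = 10))
#' @export
titration_vcc <- function(rec) {
  if (!inherits(rec, "titration_record")) {
    rec <- do.call(titration_record, as.list(rec)[c("V", "V0", "T", "A", "W")])
  }
  (rec$V - rec$V0) * rec$T * rec$A / rec$W * 100
}

# Invert the assay arithmetic: the dye volume that would report `vcc`.
titration_record_for_vcc <- function(vcc, T = 0.2, A = 10, W = 10, V0 = 0.1) {
  check_number(vcc, "vcc", lower = 0)
  titration_record(V = V0 + vcc * W / (100 * T * A), V0 = V0, T = T, A = A,
                   W = W)
}

#' True vitamin C degradation trajectory
#'
#' Evaluates the underlying kinetic law used by the synthetic generator:
#' zero-order \eqn{C = \max(C_0 - K t, 0)} (floored, since a concentration
#' cannot be negative) or first-order \eqn{C = C_0 e^{-K t}}.
#'
#' @param vcc0 Initial vitamin C content (mg/100 g), > 0.
#' @param t Storage times in days (vector allowed), >= 0.
#' @param form `"zero"` or `"first"`.
#' @param K Rate constant: mg/100 g per day (zero order) or 1/day (first
#'   order); must be >= 0.
#' @return Vitamin C content per element of `t`, non-increasing in `t`.
#' @export
simulate_true_trajectory <- function(vcc0, t, form = c("zero", "first"), K) {
  form <- match.arg(form)
  check_number(vcc0, "vcc0", lower = .Machine$double.eps)
  check_number(K, "K")
  if (K < 0) stopf("invalid kinetic parameter: rate K must be >= 0, got %g", K)
  stopifnot(is.numeric(t), all(t >= 0))
  switch(form,
         zero = pmax(vcc0 - K * t, 0),
         first = vcc0 * exp(-K * t))
}

#' Configuration of a synthetic storage study
#'
#' Defaults reproduce the design of the room-temperature (20 degC) jujube
#' storage experiment the pipeline targets: 72 fruits in 18 groups of 4,
#' spectra at 3 probe positions per fruit each day, one group titrated
#' (destructively) per day over 18 days, vitamin C declining by zero-order
#' kinetics from about 350 mg/100 g at 20.677 mg/100 g/day, multiplicative/
#' additive scatter between spectra, and late-storage decay (after day 11)
#' that disorders the spectra of 5 fruits.
#'
#' @param n_fruits,n_groups,group_size Study design counts;
#'   `n_groups * group_size` must equal `n_fruits`.
#' @param n_positions Probe positions scanned per fruit per day.
#' @param vcc0_mean,vcc0_sd Mean and sd (mg/100 g) of the initial vitamin C
#'   content, drawn truncated-normal positive.
#' @param rate_K Degradation rate constant (mg/100 g/day for `"zero"`,
#'   1/day for `"first"`).
#' @param kinetic_form `"zero"` or `"first"`.
#' @param band_centers,band_amp0,band_slope,band_sd Gaussian absorption band
#'   centers (cm-1), baseline amplitudes (AU), vitamin-C sensitivities
#'   (AU per mg/100 g; 0 for bands not coupled to vitamin C) and common band
#'   width (sd, cm-1). Defaults place vitamin-C-coupled bands at 8,330,
#'   6,900, 5,666, 5,150 and 4,060 cm-1 and fixed water-dominated bands at
#'   10,300 and 4,710 cm-1.
#' @param scatter_slope_sd Sd of the log multiplicative scatter slope per
#'   spectrum (dimensionless).
#' @param scatter_offset_sd Sd of the additive scatter offset (AU).
#' @param noise_sd Sd of white measurement noise per grid point (AU).
#' @param decay_start_day First day (1-indexed) on which a fruit can decay.
#' @param decay_prob_per_day Per-day decay hazard for an at-risk fruit.
#' @param n_decayed If non-`NULL`, condition the simulation on exactly this
#'   many decayed fruits (capped at the number of at-risk fruits); `NULL`
#'   draws per-day Bernoulli decay events unconditionally.
#' @param decay_noise_factor Noise inflation factor for spectra of decayed
#'   fruits from their decay day onward.
#' @param titer_T,dilution_A,assay_weight,blank_V0 Titration assay constants
#'   (mg/mL, dimensionless, g, mL).
#' @param titration_noise_sd Sd of titration measurement error (mg/100 g).
#' @param seed Integer seed controlling all randomness of the study.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_fruits = 72, n_groups = 18, group_size = 4,
                         n_positions = 3,
                         vcc0_mean = 350, vcc0_sd = 40,
                         rate_K = 20.677, kinetic_form = c("zero", "first"),
                         band_centers = c(10300, 8330, 6900, 5666, 5150,
                                          4710, 4060),
                         band_amp0 = c(0.15, 0.05, 0.35, 0.10, 0.30,
                                       0.25, 0.08),
                         band_slope = c(0, 8e-4, 5e-4, 6.5e-4, 4e-4,
                                        0, 3e-4),
                         band_sd = 60,
                         scatter_slope_sd = 0.05, scatter_offset_sd = 0.02,
                         noise_sd = 0.003,
                         decay_start_day = 12, decay_prob_per_day = 0.045,
                         n_decayed = 5, decay_noise_factor = 10,
                         titer_T = 0.2, dilution_A = 10, assay_weight = 10,
                         blank_V0 = 0.1,
                         titration_noise_sd = 5,
                         seed = 1L) {
  cfg <- list(
    n_fruits = check_count(n_fruits, "n_fruits"),
    n_groups = check_count(n_groups, "n_groups"),
    group_size = check_count(group_size, "group_size"),
    n_positions = check_count(n_positions, "n_positions"),
    vcc0_mean = check_number(vcc0_mean, "vcc0_mean", lower = 0),
    vcc0_sd = check_number(vcc0_sd, "vcc0_sd", lower = 0),
    rate_K = check_number(rate_K, "rate_K", lower = 0),
    kinetic_form = match.arg(kinetic_form),
    band_centers = band_centers,
    band_amp0 = band_amp0,
    band_slope = band_slope,
    band_sd = check_number(band_sd, "band_sd", lower = .Machine$double.eps),
    scatter_slope_sd = check_number(scatter_slope_sd, "scatter_slope_sd",
                                    lower = 0),
    scatter_offset_sd = check_number(scatter_offset_sd, "scatter_offset_sd",
                                     lower = 0),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
    decay_start_day = check_count(decay_start_day, "decay_start_day"),
    decay_prob_per_day = check_number(decay_prob_per_day,
                                      "decay_prob_per_day", 0, 1),
    n_decayed = if (is.null(n_decayed)) NULL else
      check_count(n_decayed, "n_decayed", lower = 0L),
    decay_noise_factor = check_number(decay_noise_factor,
                                      "decay_noise_factor", lower = 1),
    titer_T = check_number(titer_T, "titer_T", lower = .Machine$double.eps),
    dilution_A = check_number(dilution_A, "dilution_A", lower = 1),
    assay_weight = check_number(assay_weight, "assay_weight",
                                lower = .Machine$double.eps),
    blank_V0 = check_number(blank_V0, "blank_V0", lower = 0),
    titration_noise_sd = check_number(titration_noise_sd,
                                      "titration_noise_sd", lower = 0),
    seed = check_count(seed, "seed", lower = 0L)
  )
  if (cfg$n_groups * cfg$group_size != cfg$n_fruits) {
    stopf("configuration error: n_groups (%d) x group_size (%d) != n_fruits (%d)",
          cfg$n_groups, cfg$group_size, cfg$n_fruits)
  }
  nb <- length(cfg$band_centers)
  if (length(cfg$band_amp0) != nb || length(cfg$band_slope) != nb) {
    stopf("configuration error: band_centers, band_amp0 and band_slope must have equal length")
  }
  if (any(cfg$band_centers <= 0)) {
    stopf("configuration error: band centers must be positive wavenumbers")
  }
  class(cfg) <- "study_config"
  cfg
}

# Deterministic spectral response: absorbance(w) = c0(w) + sens(w) * vcc.
# c0 is the baseline plus vcc-independent band content, sens the vitamin C
# sensitivity spectrum (sum of Gaussians at the coupled band centers).
synth_response <- function(grid, config) {
  G <- exp(-outer(grid, config$band_centers, "-")^2 / (2 * config$band_sd^2))
  baseline <- 0.2 + 6e-5 * (grid[1] - grid)
  list(c0 = baseline + drop(G %*% config$band_amp0),
       sens = drop(G %*% config$band_slope))
}

#' Simulate one NIR spectrum for a given vitamin C content
#'
#' Generative model: a smooth baseline plus Gaussian absorption bands, with
#' the amplitudes of the vitamin-C-coupled bands affine in `vcc`, all scaled
#' by a per-spectrum multiplicative scatter slope, shifted by an additive
#' scatter offset, and perturbed by white noise:
#' \deqn{A(w) = s \, [c_0(w) + d(w)\,vcc] + o + \epsilon(w)}
#' with \eqn{s = e^{Z}}, \eqn{Z \sim N(0, \sigma_{slope})},
#' \eqn{o \sim N(0, \sigma_{offset})},
#' \eqn{\epsilon \sim N(0, \sigma_{noise} \cdot \mathrm{noisescale})}.
#' Draws come from R's current RNG stream, so the output is deterministic
#' given the RNG state (and exactly reproducible across calls when all three
#' sds are zero).
#'
#' @param vcc Vitamin C content (mg/100 g), >= 0.
#' @param grid Wavenumber grid (see [spectrum_grid()]).
#' @param config A [study_config()].
#' @param noise_scale Multiplier on `noise_sd` (used to disorder the spectra
#'   of decayed fruits).
#' @return Absorbance vector of `length(grid)`.
#' @export
simulate_spectrum <- function(vcc, grid, config, noise_scale = 1) {
  check_number(vcc, "vcc", lower = 0)
  stopifnot(inherits(config, "study_config"))
  resp <- synth_response(grid, config)
  slope <- exp(stats::rnorm(1, 0, config$scatter_slope_sd))
  offset <- stats::rnorm(1, 0, config$scatter_offset_sd)
  noise <- stats::rnorm(length(grid), 0, config$noise_sd * noise_scale)
  slope * (resp$c0 + resp$sens * vcc) + offset + noise
}

# Assign decay days. Unconditional: independent per-day Bernoulli(p) from
# decay_start_day up to each fruit's titration day. Conditional (n_decayed
# given): which fruits decay is drawn with probability proportional to their
# Bernoulli decay probability over their at-risk window, and the decay day
# within the window from the correspondingly truncated geometric.
assign_decay <- function(tday, config) {
  n <- length(tday)
  start <- config$decay_start_day
  p <- config$decay_prob_per_day
  exposure <- pmax(0L, tday - start + 1L)
  decay_day <- rep(NA_integer_, n)
  draw_day <- function(expo) {
    j <- seq_len(expo)
    w <- if (p > 0) p * (1 - p)^(j - 1) else rep(1, expo)
    start + sample.int(expo, 1L, prob = w) - 1L
  }
  if (is.null(config$n_decayed)) {
    for (f in which(exposure > 0L)) {
      u <- stats::runif(exposure[f])
      hit <- which(u < p)
      if (length(hit) > 0L) decay_day[f] <- start + hit[1L] - 1L
    }
  } else {
    eligible <- which(exposure > 0L)
    k <- min(config$n_decayed, length(eligible))
    if (k > 0L) {
      w <- 1 - (1 - p)^exposure[eligible]
      if (all(w == 0)) w <- exposure[eligible]
      chosen <- eligible[sample.int(length(eligible), k, prob = w)]
      for (f in chosen) decay_day[f] <- draw_day(exposure[f])
    }
  }
  decay_day
}

#' Generate a complete synthetic storage study
#'
#' Runs the destructive longitudinal design end to end: initial vitamin C
#' contents are drawn, every surviving fruit is scanned at `n_positions`
#' positions each day, group `g` is titrated on day `g` (so a fruit has
#' spectra only for days up to its titration day), decay events disorder
#' late-storage spectra, and titration records are produced by inverting the
#' assay arithmetic from the true content plus measurement noise. Storage
#' time is `t = day - 1` (day 1 is the arrival / t = 0 state).
#'
#' @param config A [study_config()].
#' @param grid Wavenumber grid (defaults to the instrument grid).
#' @return A list of class `study_dataset` with elements `grid`, `spectra`
#'   (an [nir_spectra] of all fruit-day-position scans), `manifest` (fruit,
#'   group, weight, titration day, decayed flag, decay day, true initial
#'   content), `titrations` (assay records plus the measured concentration)
#'   and `truth` (true content per fruit-day), plus the `config`.
#' @export
generate_study <- function(config = study_config(), grid = spectrum_grid()) {
  stopifnot(inherits(config, "study_config"))
  with_local_seed(config$seed, {
    n <- config$n_fruits
    fruit <- sprintf("F%02d", seq_len(n))
    group <- rep(seq_len(config$n_groups), each = config$group_size)
    tday <- group
    weight <- stats::runif(n, 25, 30)
    vcc0 <- stats::rnorm(n, config$vcc0_mean, config$vcc0_sd)
    while (any(vcc0 <= 0)) {
      bad <- vcc0 <= 0
      vcc0[bad] <- stats::rnorm(sum(bad), config$vcc0_mean, config$vcc0_sd)
    }
    decay_day <- assign_decay(tday, config)

    manifest <- data.frame(fruit = fruit, group = group, weight = weight,
                           titration_day = tday,
                           decayed = !is.na(decay_day),
                           decay_day = decay_day,
                           vcc0_true = vcc0,
                           stringsAsFactors = FALSE)

    truth <- do.call(rbind, lapply(seq_len(n), function(f) {
      day <- seq_len(tday[f])
      data.frame(fruit = fruit[f], day = day, t = day - 1,
                 vcc_true = simulate_true_trajectory(
                   vcc0[f], day - 1, config$kinetic_form, config$rate_K),
                 stringsAsFactors = FALSE)
    }))

    resp <- synth_response(grid, config)
    n_spec <- sum(tday) * config$n_positions
    vals <- matrix(0, n_spec, length(grid))
    meta <- data.frame(fruit = character(n_spec), day = integer(n_spec),
                       position = integer(n_spec), stringsAsFactors = FALSE)
    r <- 0L
    for (f in seq_len(n)) {
      for (day in seq_len(tday[f])) {
        vcc_day <- truth$vcc_true[truth$fruit == fruit[f] & truth$day == day]
        scale <- if (!is.na(decay_day[f]) && day >= decay_day[f]) {
          config$decay_noise_factor
        } else 1
        shape <- resp$c0 + resp$sens * vcc_day
        for (pos in seq_len(config$n_positions)) {
          r <- r + 1L
          slope <- exp(stats::rnorm(1, 0, config$scatter_slope_sd))
          offset <- stats::rnorm(1, 0, config$scatter_offset_sd)
          vals[r, ] <- slope * shape + offset +
            stats::rnorm(length(grid), 0, config$noise_sd * scale)
          meta$fruit[r] <- fruit[f]
          meta$day[r] <- day
          meta$position[r] <- pos
        }
      }
    }

    vcc_final <- truth$vcc_true[match(paste(fruit, tday),
                                      paste(truth$fruit, truth$day))]
    vcc_meas <- pmax(0, vcc_final +
                       stats::rnorm(n, 0, config$titration_noise_sd))
    titrations <- data.frame(
      fruit = fruit, day = tday,
      V = config$blank_V0 + vcc_meas * config$assay_weight /
        (100 * config$titer_T * config$dilution_A),
      V0 = config$blank_V0, T = config$titer_T, A = config$dilution_A,
      W = config$assay_weight,
      vcc_measured = vcc_meas,
      stringsAsFactors = FALSE)

    structure(list(grid = grid,
                   spectra = nir_spectra(vals, grid, meta),
                   manifest = manifest, titrations = titrations,
                   truth = truth, config = config),
              class = "study_dataset")
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset> %d fruits in %d groups, %d spectra, ",
                     "%d titrations, %d decayed\n"),
              nrow(x$manifest), max(x$manifest$group), nrow(x$spectra$values),
              nrow(x$titrations), sum(x$manifest$decayed)))
  invisible(x)
}

#' Exact models implied by a noise-free synthetic study
#'
#' For a study generated with zero scatter and zero noise, the absorbance at
#' any wavenumber is exactly affine in the vitamin C content, so a
#' single-wavenumber calibration model inverts the generator exactly, and
#' the kinetic model equals the generating law. Useful for end-to-end
#' round-trip validation.
#'
#' @param config A [study_config()].
#' @param grid Wavenumber grid.
#' @param wavenumber Wavenumber (cm-1) at which to anchor the calibration;
#'   defaults to the grid point nearest the most vitamin-C-sensitive band
#'   center.
#' @return A list with `mlr` (an exact [mlr_model()]) and `kinetic` (an
#'   exact zero- or first-order model matching `config$kinetic_form`).
#' @export
true_models <- function(config = study_config(), grid = spectrum_grid(),
                        wavenumber = NULL) {
  stopifnot(inherits(config, "study_config"))
  resp <- synth_response(grid, config)
  if (is.null(wavenumber)) {
    best <- config$band_centers[which.max(abs(config$band_slope))]
    wavenumber <- grid[which.min(abs(grid - best))]
  }
  i <- which(grid == wavenumber)
  if (length(i) != 1L) stopf("wavenumber %g is not on the grid", wavenumber)
  d <- resp$sens[i]
  if (abs(d) < 1e-12) {
    stopf("wavenumber %g has no vitamin C sensitivity in this configuration",
          wavenumber)
  }
  mlr <- mlr_model(intercept = -resp$c0[i] / d,
                   coefficients = stats::setNames(1 / d, wavenumber),
                   region = "VNIR")
  kinetic <- if (config$kinetic_form == "zero") {
    zero_order_model(a = 0, b = 1, K = config$rate_K)
  } else {
    first_order_model(C0 = NA_real_, K = config$rate_K)
  }
  list(mlr = mlr, kinetic = kinetic)
}
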