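test_that("split_samples is seeded, disjoint and excludes decayed fruits", {
  st <- generate_study()
  sp <- split_samples(st, split_spec(seed = 5))
  expect_length(sp$calibration, 50)
  expect_length(sp$prediction, 17)
  expect_length(intersect(sp$calibration, sp$prediction), 0)
  decayed <- st$manifest$fruit[st$manifest$decayed]
  expect_length(intersect(c(sp$calibration, sp$prediction), decayed), 0)
  # together they cover all 67 non-decayed fruits
  expect_setequal(c(sp$calibration, sp$prediction),
                  setdiff(st$manifest$fruit, decayed))
  # same seed, same split; insufficient samples error
  expect_identical(split_samples(st, split_spec(seed = 5)), sp)
  expect_error(split_samples(st, split_spec(60, 17)), "split error")
})

test_that("RC selection finds the informative column and breaks ties low", {
  set.seed(21)
  wn <- spectrum_grid(4800, 4000, 8)
  X <- matrix(rnorm(40 * length(wn), 0.5, 0.05), 40)
  k <- 37
  y <- 3 * X[, k]
  expect_equal(select_wavenumbers_rc(X, y, 1, wn), wn[k])
  # exact |RC| tie via an orthogonal design: the centered columns are
  # mutually orthogonal with equal norms, so the ridge system is diagonal
  # and the twin responses produce bit-identical coefficients
  Xo <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  yo <- Xo[, 1] + Xo[, 2]
  sel_tie <- select_wavenumbers_rc(Xo, yo, 1, c(4016, 4008, 4000),
                                   lambda = 1)
  expect_equal(sel_tie, 4008)  # the lower of the two tied wavenumbers
  # asking for more maxima than exist is an informative error
  Xs <- matrix(rnorm(20 * 3, 0, 1), 20)
  expect_error(select_wavenumbers_rc(Xs, rnorm(20), 4, c(4016, 4008, 4000)),
               "local \\|RC\\| maxima")
})

test_that("RC selection recovers planted band centers on synthetic spectra", {
  st <- generate_study(noise_free_config())
  tab <- titration_day_spectra(st)
  lw <- restrict_region(tab$spectra, "LWNIR")
  sel <- select_wavenumbers_rc(lw, tab$vcc, 5)
  expect_length(sel, 5)
  expect_true(all(abs(sel - expected_lwnir_bands) <= 8))
})

test_that("fit_mlr matches a normal-equations oracle and reports its CI", {
  set.seed(31)
  n <- 50
  X <- matrix(rnorm(n * 5, 0.5, 0.1), n)
  wn <- c(8328, 6896, 5664, 5152, 4056)
  beta <- c(1400, 1500, 2100, -3500, -280, 30)
  y <- drop(cbind(1, X) %*% beta) + rnorm(n, 0, 10)
  fit <- fit_mlr(X, y, wn)
  oracle <- drop(solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y)))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
               tolerance = 1e-8)
  # CI of the mean fitted value against the closed form
  res <- y - predict_vcc(fit, X)
  s <- sqrt(sum(res^2) / (n - 6))
  half <- qt(0.975, n - 6) * s / sqrt(n)
  expect_equal(fit$ci_mean_high - fit$ci_mean_low, 2 * half,
               tolerance = 1e-10)
  expect_equal((fit$ci_mean_high + fit$ci_mean_low) / 2, mean(y - res),
               tolerance = 1e-10)
  # exact affine data are interpolated exactly
  y0 <- drop(cbind(1, X) %*% beta)
  fit0 <- fit_mlr(X, y0, wn)
  expect_equal(unname(c(fit0$intercept, fit0$coefficients)), beta,
               tolerance = 1e-8)
  # rank-deficient designs are refused with the offending columns named
  Xbad <- cbind(X[, 1:4], X[, 4])
  expect_error(fit_mlr(Xbad, y, wn), "collinearity")
  expect_error(fit_mlr(X[1:5, ], y[1:5], wn), "more samples")
})

test_that("predict_vcc evaluates published coefficients correctly", {
  ref <- reference_models()$mlr
  # all-zero absorbances return the intercept
  expect_equal(predict_vcc(ref, rep(0, 5)), 1409.098)
  # unit absorbance on X3 only: hand arithmetic on the printed coefficients
  expect_equal(predict_vcc(ref, c(0, 0, 1, 0, 0)), 1409.098 - 3501.009)
  # zero coefficients predict the intercept for every sample
  flat <- mlr_model(5, c("8328" = 0, "6896" = 0))
  expect_equal(predict_vcc(flat, matrix(rnorm(10), 5)), rep(5, 5))
  # grid mismatch is an error
  grid <- spectrum_grid(5000, 4000, 8)
  sp <- nir_spectra(matrix(0.1, 1, length(grid)), grid,
                    data.frame(fruit = "F01", day = 1L, position = 1L))
  expect_error(predict_vcc(ref, sp), "grid mismatch")
})

test_that("evaluation metrics match a hand-computed oracle", {
  model <- mlr_model(0, c("8328" = 1))
  # perfect fit
  X <- matrix(c(10, 20, 30, 40), 4)
  y <- c(10, 20, 30, 40)
  m <- evaluate_calibration(model, list(X = X, vcc = y),
                            list(X = X, vcc = y))
  expect_equal(m$Rc, 1)
  expect_equal(m$RMSEC, 0)
  # constant shift: R stays 1, RMSE equals the shift
  m2 <- evaluate_calibration(model, list(X = X + 3, vcc = y),
                             list(X = X, vcc = y))
  expect_equal(m2$Rc, 1)
  expect_equal(m2$RMSEC, 3)
  # small worked set against explicit sum formulas
  pred <- c(12, 18, 33, 37)
  obs <- c(10, 20, 30, 40)
  mh <- evaluate_calibration(model, list(X = matrix(pred, 4), vcc = obs),
                             list(X = matrix(pred, 4), vcc = obs))
  r_hand <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(mh$Rc, r_hand, tolerance = 1e-12)
  expect_equal(mh$RMSEC, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  # constant predictions flag the correlation as undefined
  mc <- evaluate_calibration(mlr_model(7, c("8328" = 0)),
                             list(X = X, vcc = y), list(X = X, vcc = y))
  expect_true(mc$r_undefined)
  expect_true(is.na(mc$Rc))
})

test_that("pretreatment harness rows keep order and MSC beats raw on scatter", {
  cfg <- study_config(scatter_slope_sd = 0.2, scatter_offset_sd = 0.1,
                      noise_sd = 0.002, seed = 3)
  st <- generate_study(cfg)
  tab <- compare_pretreatments(st, c("raw", "sg", "msc", "d1", "d2"),
                               region = "LWNIR", n_select = 5)
  expect_identical(tab$method, c("raw", "sg", "msc", "d1", "d2"))
  expect_gt(tab$Rp[tab$method == "msc"], tab$Rp[tab$method == "raw"])
  # single-method call gives a single row
  one <- compare_pretreatments(st, "msc", region = "LWNIR", n_select = 5)
  expect_equal(nrow(one), 1L)
})

test_that("the noise-free calibration pipeline reconstructs the truth", {
  st <- generate_study(noise_free_config(seed = 9))
  # one wavenumber carries all information in the noise-free limit (more
  # would be exactly collinear)
  tab <- compare_pretreatments(st, c("raw", "sg", "msc", "d1", "d2"),
                               region = "LWNIR", n_select = 1)
  expect_true(all(tab$Rc > 0.999))
  expect_true(all(tab$Rp > 0.999))
  # methods that preserve the affine absorbance-content relation
  # interpolate exactly; MSC's normalization leaves mild curvature
  linear <- tab$method %in% c("raw", "sg", "d1", "d2")
  expect_true(all(tab$RMSEC[linear] < 1e-8))
})

test_that("model fitting never reads prediction-set responses", {
  st <- generate_study(study_config(seed = 13))
  split <- split_samples(st, split_spec(seed = 2))
  res1 <- calibrate_study(st, "msc", "LWNIR", 5, split)
  # scrambling prediction-set titration values must leave the model intact
  st2 <- st
  pred_rows <- st2$titrations$fruit %in% split$prediction
  st2$titrations$vcc_measured[pred_rows] <-
    rev(st2$titrations$vcc_measured[pred_rows]) + 100
  res2 <- calibrate_study(st2, "msc", "LWNIR", 5, split)
  expect_identical(res1$model$intercept, res2$model$intercept)
  expect_identical(res1$model$coefficients, res2$model$coefficients)
  expect_identical(res1$metrics$Rc, res2$metrics$Rc)
})

test_that("RMSEC shrinks with more wavenumbers while Rp need not improve", {
  cfg <- study_config(seed = 17)
  st <- generate_study(cfg)
  split <- split_samples(st, split_spec(seed = 4))
  ns <- c(2, 4, 6)
  runs <- lapply(ns, function(n) calibrate_study(st, "raw", "LWNIR", n, split))
  rmsec <- vapply(runs, function(r) r$metrics$RMSEC, 0)
  expect_true(all(diff(rmsec) <= 1e-9))
})
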