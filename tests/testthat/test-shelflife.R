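test_that("combined prediction composes calibration and kinetics", {
  ref <- reference_models()
  # day-0 absorbances all zero, t = 0: hand composition of the printed forms
  expect_equal(combined_predict(ref$mlr, ref$zero, rep(0, 5), 0),
               338.787 + 0.044 * 1409.098)
  # one extra day of storage costs exactly K
  v1 <- combined_predict(ref$mlr, ref$zero, rep(0, 5), 3)
  v2 <- combined_predict(ref$mlr, ref$zero, rep(0, 5), 4)
  expect_equal(v1 - v2, 20.677)
  # degenerate kinetics: constant a regardless of the spectrum
  flatk <- suppressWarnings(zero_order_model(250, 0, 0))
  set.seed(61)
  expect_equal(combined_predict(ref$mlr, flatk, rnorm(5), 7), 250)
  expect_error(combined_predict(ref$mlr, ref$zero, rep(0, 5), -1), "t must")
})

test_that("storage-time inversion: printed vs algebraic forms", {
  ref <- reference_models()
  # the literal published inversion at the origin
  expect_equal(invert_storage_time(ref$zero, 0, 0, "as_printed"), 17.128)
  # the exact algebraic inversion of the published zero-order model
  alg <- invert_storage_time(ref$zero, 0, 0, "algebraic")
  expect_equal(alg, 338.787 / 20.677, tolerance = 1e-12)
  # the two deliberately disagree (rounded published coefficients)
  expect_gt(abs(alg - 17.128), 0.5)
  expect_error(
    invert_storage_time(suppressWarnings(zero_order_model(10, 1, 0)), 0, 0),
    "not invertible")
})

test_that("algebraic inversion round-trips predict_kinetic exactly", {
  set.seed(62)
  for (i in 1:25) {
    m <- zero_order_model(a = rnorm(1, 300, 100), b = rnorm(1, 0.5, 0.5),
                          K = runif(1, 0.1, 40))
    v0 <- runif(1, 50, 500)
    t <- runif(1, 0, 30)
    vcc <- predict_kinetic(m, v0, t)
    expect_equal(invert_storage_time(m, v0, vcc), t, tolerance = 1e-10)
  }
})

test_that("shelf life from spectra separates stages and flags negatives", {
  ref <- reference_models()
  # absorbances chosen so the predicted contents sit inside the model's
  # degrading range (positive storage-time fixed point)
  x0 <- c(0, 0, 0.32, 0, 0)
  xt <- c(0, 0, 0.35, 0, 0)
  p_alg <- shelf_life_from_spectra(ref$mlr, ref$zero, x0, xt, "algebraic")
  p_prt <- shelf_life_from_spectra(ref$mlr, ref$zero, x0, xt, "as_printed")
  # the method toggle changes only the inversion, not the NIR predictions
  expect_identical(p_alg$vcc0_used, p_prt$vcc0_used)
  expect_identical(p_alg$vcc_used, p_prt$vcc_used)
  expect_equal(p_alg$vcc0_used, predict_vcc(ref$mlr, x0))
  # equal spectra give the fixed point of the inversion
  p_eq <- shelf_life_from_spectra(ref$mlr, ref$zero, x0, x0, "algebraic")
  v <- predict_vcc(ref$mlr, x0)
  expect_equal(p_eq$t_est, (338.787 + 0.044 * v - v) / 20.677,
               tolerance = 1e-10)
  expect_equal(predict_kinetic(ref$zero, v, p_eq$t_est), v,
               tolerance = 1e-10)
  # a day-t spectrum implying more vitamin C than day 0 is flagged
  p_neg <- shelf_life_from_spectra(mlr_model(0, c("8328" = 1)),
                                   zero_order_model(0, 1, 10),
                                   100, 150, "algebraic")
  expect_true(p_neg$negative)
  expect_equal(p_neg$t_est, -5)
})

test_that("end-to-end storage-day recovery on a noise-free study", {
  cfg <- noise_free_config(seed = 7)
  st <- generate_study(cfg)
  tm <- true_models(cfg)
  avg <- average_replicates(st$spectra)
  day1 <- match(paste(avg$meta$fruit, 1L), paste(avg$meta$fruit, avg$meta$day))
  v0_true <- st$manifest$vcc0_true[match(avg$meta$fruit, st$manifest$fruit)]
  tru <- st$truth$vcc_true[match(paste(avg$meta$fruit, avg$meta$day),
                                 paste(st$truth$fruit, st$truth$day))]
  for (i in seq_len(nrow(avg$meta))) {
    pred <- shelf_life_from_spectra(tm$mlr, tm$kinetic,
                                    avg[day1[i]], avg[i], "algebraic")
    if (tru[i] > 0) {
      # linear regime: the true storage day is recovered exactly
      expect_equal(pred$t_est, avg$meta$day[i] - 1, tolerance = 1e-6, ignore_attr = TRUE)
    } else {
      # floored trajectories invert to the zero-crossing time of the line
      expect_equal(pred$t_est, v0_true[i] / cfg$rate_K, tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("safe storage time is a monotone threshold crossing", {
  ref <- reference_models()
  # zero threshold at zero initial content: the line's root
  expect_equal(safe_storage_time(ref$zero, 0, 0), 338.787 / 20.677,
               tolerance = 1e-12)
  # definition: threshold equal to the content at t* returns t*
  tstar <- 6.5
  thr <- predict_kinetic(ref$zero, 300, tstar)
  expect_equal(safe_storage_time(ref$zero, 300, thr), tstar,
               tolerance = 1e-10)
  # strictly decreasing in threshold and in K
  expect_gt(safe_storage_time(ref$zero, 300, 0),
            safe_storage_time(ref$zero, 300, 50))
  m2 <- zero_order_model(338.787, 0.044, 2 * 20.677)
  expect_equal(safe_storage_time(m2, 0, 0),
               safe_storage_time(ref$zero, 0, 0) / 2, tolerance = 1e-12)
  expect_error(
    safe_storage_time(suppressWarnings(zero_order_model(10, 1, -1)), 100),
    "non-degrading")
})

test_that("a realistic pipeline estimates shelf life near 15 days", {
  # with the default generator (initial content about 350 mg/100 g,
  # zero-order rate about 20.7 mg/100 g/day) the vitamin C pool is
  # exhausted in roughly 15-19 days
  st <- generate_study()
  res <- calibrate_study(st, "msc", "LWNIR", 5)
  kin <- kinetics_inputs(st, res)
  zero <- fit_zero_order(kin$vcc, kin$vcc0, kin$t)
  t_safe <- safe_storage_time(zero, mean(kin$vcc0))
  expect_gt(t_safe, 12)
  expect_lt(t_safe, 22)
})
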