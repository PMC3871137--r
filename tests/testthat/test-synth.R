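test_that("titration arithmetic converts dye volumes to mg/100 g", {
  # direct arithmetic on a worked record
  rec <- titration_record(V = 5.0, V0 = 0.1, T = 0.2, A = 10, W = 10)
  expect_equal(titration_vcc(rec), 98.0)
  # zero dye difference means zero vitamin C
  expect_equal(titration_vcc(titration_record(2, 2, 0.3, 5, 12)), 0)
  # homogeneity: doubling the sample weight halves the result
  v10 <- titration_vcc(titration_record(5, 0.1, 0.2, 10, 10))
  v20 <- titration_vcc(titration_record(5, 0.1, 0.2, 10, 20))
  expect_equal(v20, v10 / 2)
  # invalid records are rejected
  expect_error(titration_record(5, 0.1, 0.2, 10, 0), "weight")
  expect_error(titration_record(5, 0.1, 0, 10, 10), "titer")
  expect_error(titration_record(1, 2, 0.2, 10, 10), "blank")
})

test_that("titration records round-trip through the assay arithmetic", {
  for (vcc in c(0, 3.25, 98, 350, 398.287)) {
    rec <- jujubeNIR:::titration_record_for_vcc(vcc)
    expect_equal(titration_vcc(rec), vcc, tolerance = 1e-12)
  }
})

test_that("true degradation trajectories follow the kinetic laws", {
  # first-order value at t = 0 is the initial content
  expect_equal(simulate_true_trajectory(550.58, 0, "first", 0.164), 550.58)
  # zero-order hand arithmetic and floor at zero
  expect_equal(simulate_true_trajectory(413.54, 10, "zero", 20.677), 206.77)
  expect_equal(simulate_true_trajectory(300, 20, "zero", 20.677), 0)
  # non-increasing in t for both forms
  t <- seq(0, 25, by = 0.5)
  for (form in c("zero", "first")) {
    traj <- simulate_true_trajectory(350, t, form, 2)
    expect_true(all(diff(traj) <= 0))
  }
  expect_error(simulate_true_trajectory(350, 1, "zero", -1), "K")
})

test_that("simulate_spectrum is deterministic and vitamin-C-coupled", {
  cfg <- noise_free_config()
  grid <- spectrum_grid()
  s1 <- simulate_spectrum(100, grid, cfg)
  s2 <- simulate_spectrum(100, grid, cfg)
  expect_identical(s1, s2)  # all noise sds zero
  # same RNG state gives identical draws even with noise
  cfgn <- study_config()
  set.seed(42); a <- simulate_spectrum(100, grid, cfgn)
  set.seed(42); b <- simulate_spectrum(100, grid, cfgn)
  expect_identical(a, b)
  # the vcc difference spectrum is supported only on the coupled bands
  d <- simulate_spectrum(200, grid, cfg) - simulate_spectrum(100, grid, cfg)
  coupled <- cfg$band_centers[cfg$band_slope > 0]
  far <- apply(abs(outer(grid, coupled, "-")), 1, min) > 6 * cfg$band_sd
  expect_true(all(abs(d[far]) < 1e-9))
  expect_true(max(abs(d)) > 1e-3)
})

test_that("generate_study respects the destructive-sampling design", {
  st <- generate_study()
  m <- st$manifest
  expect_equal(nrow(m), 72)
  expect_equal(max(m$group), 18)
  expect_equal(as.integer(table(m$group)), rep(4L, 18))
  # group k carries k daily spectrum sets of 3 positions each
  for (f in m$fruit) {
    sub <- st$spectra$meta[st$spectra$meta$fruit == f, ]
    k <- m$group[m$fruit == f]
    expect_equal(sort(unique(sub$day)), seq_len(k))
    expect_equal(nrow(sub), 3L * k)
  }
  # total spectrum sets = group_size * sum(1..n_groups)
  expect_equal(nrow(st$spectra$values), 4 * sum(1:18) * 3)
  # spectra exist only up to the titration day
  expect_true(all(st$spectra$meta$day <=
                    m$titration_day[match(st$spectra$meta$fruit, m$fruit)]))
  # default conditions on exactly 5 decayed fruits, all after day 11
  expect_equal(sum(m$decayed), 5)
  expect_true(all(m$decay_day[m$decayed] >= 12))
  expect_true(all(m$decay_day[m$decayed] <= m$titration_day[m$decayed]))
})

test_that("generate_study is reproducible by seed and sensitive to it", {
  cfg <- small_config(seed = 10)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$spectra$values, b$spectra$values)
  expect_identical(a$titrations, b$titrations)
  c <- generate_study(small_config(seed = 11))
  expect_false(identical(a$spectra$values, c$spectra$values))
})

test_that("smallest design and noise-free titration round trip", {
  cfg <- study_config(n_fruits = 2, n_groups = 2, group_size = 1,
                      n_positions = 1, noise_sd = 0, scatter_slope_sd = 0,
                      scatter_offset_sd = 0, titration_noise_sd = 0,
                      n_decayed = 0, seed = 2)
  st <- generate_study(cfg)
  expect_equal(nrow(st$manifest), 2)
  expect_equal(nrow(st$spectra$values), 3)  # 1 + 2 fruit-days
  # noise-free: evaluating the assay on each record recovers the true value
  for (i in seq_len(nrow(st$titrations))) {
    rec <- titration_record(st$titrations$V[i], st$titrations$V0[i],
                            st$titrations$T[i], st$titrations$A[i],
                            st$titrations$W[i])
    tru <- st$truth$vcc_true[st$truth$fruit == st$titrations$fruit[i] &
                               st$truth$day == st$titrations$day[i]]
    expect_equal(titration_vcc(rec), tru, tolerance = 1e-10)
  }
})

test_that("unconditioned Bernoulli decay responds to its hazard", {
  cfg0 <- study_config(n_decayed = NULL, decay_prob_per_day = 0, seed = 3)
  expect_equal(sum(generate_study(cfg0)$manifest$decayed), 0)
  cfg1 <- study_config(n_decayed = NULL, decay_prob_per_day = 1, seed = 3)
  st1 <- generate_study(cfg1)
  # every fruit still alive on the start day decays exactly then
  m <- st1$manifest
  at_risk <- m$titration_day >= 12
  expect_true(all(m$decayed[at_risk]))
  expect_true(all(m$decay_day[at_risk] == 12))
  expect_true(!any(m$decayed[!at_risk]))
})

test_that("config invariants are enforced", {
  expect_error(study_config(n_fruits = 71), "n_groups")
  expect_error(study_config(noise_sd = -1), "noise_sd")
  expect_error(study_config(decay_prob_per_day = 1.5), "decay_prob_per_day")
  expect_error(study_config(band_amp0 = c(1, 2)), "equal length")
})

test_that("true_models invert a noise-free generator exactly", {
  cfg <- noise_free_config(seed = 4)
  st <- generate_study(cfg)
  tm <- true_models(cfg)
  tab <- titration_day_spectra(st)
  pred <- predict_vcc(tm$mlr, tab$spectra)
  expect_equal(pred, unname(tab$vcc), tolerance = 1e-8,
               ignore_attr = TRUE)
})
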