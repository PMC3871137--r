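# Shared fixtures: deterministic configs and independent oracles.

# Study with every stochastic component switched off: spectra and titrations
# are exact functions of the generating kinetics.
noise_free_config <- function(seed = 7, ...) {
  study_config(noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
               titration_noise_sd = 0, seed = seed, ...)
}

# A small fast design (6 fruits, 3 groups) for I/O and plumbing tests.
small_config <- function(seed = 1, ...) {
  study_config(n_fruits = 6, n_groups = 3, group_size = 2, n_positions = 2,
               seed = seed, ...)
}

# Brute-force Savitzky-Golay oracle: an independent per-window polynomial
# least-squares fit at every interior point (no shared kernel).
sg_oracle <- function(x, wavenumbers, half_window, poly_order, deriv_order) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half_window + 1):(n - half_window)) {
    j <- (i - half_window):(i + half_window)
    dw <- wavenumbers[j] - wavenumbers[i]
    A <- outer(dw, 0:poly_order, `^`)
    beta <- qr.solve(A, x[j])
    out[i] <- beta[deriv_order + 1] * factorial(deriv_order)
  }
  out
}

expected_lwnir_bands <- c(8330, 6900, 5666, 5150, 4060)
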