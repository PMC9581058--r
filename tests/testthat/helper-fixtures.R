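# Small, fast grid for unit tests (coarser than the measurement default so
# fits stay in the millisecond range)
small_grid <- function() tcspc_grid(delta_t = 0.05, period = 25)

# The measurement-resolution grid of the standard simulation conditions
full_grid <- function() tcspc_grid(delta_t = 0.016, period = 25)

default_params <- function(n_hat = 2000) decay_params(tau = 2, b = 0.2, n_hat = n_hat)

# Shifted-Gamma IRF with a FWHM of ~0.58 ns, the width of a typical
# diode-laser confocal IRF
test_irf <- function(t0 = 1) gamma_irf(t0 = t0, rho = 3, kappa = 5.855)

# Noise-free integer histogram from model expectations (large counts so
# rounding is negligible)
noise_free_histogram <- function(params, grid, scale = 1) {
  tcspc_histogram(round(expected_counts(params, grid) * scale), grid)
}
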