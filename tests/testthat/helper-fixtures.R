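# Shared fixtures. Heavier simulated objects are memoised so several test
# files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_props <- function() optical_properties(0.1, 10)

# coarse Gaussian-shaped DTOF used by several moment tests
gaussian_dtof <- function(mu = 1500, sigma = 300, bw = 2, span = 6) {
  t <- seq(mu - span * sigma, mu + span * sigma, by = bw)
  dtof(t, 1e6 * stats::dnorm(t, mu, sigma))
}

# small noiseless sweep with full qualitative structure (reused widely):
# 15 x 16 x 3 positions, mu_s' = 10 cm^-1 default phantom
qualitative_maps <- function() {
  memo("qual_maps", {
    ds <- simulate_sweep(
      default_props(), optode_geometry(),
      sweep_grid(x_extent_mm = 70, x_step_mm = 5, y_extent_mm = 10,
                 y_step_mm = 5, z_extent_mm = 30, z_step_mm = 2),
      inclusion(),
      noise_config(poisson = FALSE, irf_fwhm_ps = 650),
      time_grid(10000, 2048)
    )
    assemble_maps(ds)
  })
}

# tiny noisy dataset (with replicates) for identity / container tests
noisy_dataset <- function() {
  memo("noisy_ds", {
    simulate_sweep(
      default_props(), optode_geometry(),
      sweep_grid(x_extent_mm = 16, x_step_mm = 8, y_extent_mm = 2,
                 y_step_mm = 2, z_extent_mm = 8, z_step_mm = 4),
      inclusion(),
      noise_config(counts_per_dtof = 1e5, n_replicates = 20, irf_fwhm_ps = 650),
      time_grid(10000, 1024),
      seed = 42
    )
  })
}
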