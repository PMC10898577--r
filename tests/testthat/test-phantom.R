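test_that("sweep grid matches the configured extents, steps and origin", {
  g <- sweep_grid()
  expect_equal(length(g$x_mm), floor(75 / 2) + 1)
  expect_equal(length(g$y_mm), floor(20 / 1) + 1)
  expect_equal(length(g$z_mm), floor(35 / 2) + 1)
  expect_true(all(g$positions$z_mm > 0))
  expect_equal(mean(range(g$x_mm)), 0) # centred on the detector midpoint
  expect_equal(nrow(g$positions), 38 * 21 * 18)
})

test_that("optode geometry pairs two far and two near channels symmetrically", {
  geo <- optode_geometry(3, 2.5)
  ch <- geo$channels
  expect_equal(sort(ch$separation), c(2.5, 2.5, 3, 3))
  expect_equal(ch$role[ch$name %in% c("left_2", "right_1")], c("far", "far"))
  expect_equal(ch$role[ch$name %in% c("left_1", "right_2")], c("near", "near"))
  # symmetric about the detector midpoint
  expect_equal(ch$source_x[ch$source == "left"], -ch$source_x[ch$source == "right"])
})

test_that("inclusion volume is the cylinder volume", {
  inc <- inclusion(3, 5, dmu_a = 1)
  expect_equal(inc$volume_cm3, pi * 0.15^2 * 0.5)
  expect_equal(inc$strength, inc$volume_cm3)
})

test_that("IRF convolution: delta identity, commutativity, mass preservation", {
  tg <- time_grid(8000, 1024)
  r <- reflectance_td(default_props(), 3, tg)
  delta <- c(1, rep(0, tg$n_bins - 1))
  expect_equal(apply_irf(r, delta, tg), r, tolerance = 1e-10)

  i1 <- gaussian_irf(tg, 400); i2 <- gaussian_irf(tg, 600)
  a <- apply_irf(apply_irf(r, i1, tg), i2, tg)
  b <- apply_irf(apply_irf(r, i2, tg), i1, tg)
  expect_equal(a, b, tolerance = 1e-9)
  expect_lt(abs(sum(a) / sum(r) - 1), 1e-4)
})

test_that("Poisson sampling has the right mean, variance and support", {
  tg <- time_grid(1000, 16)
  curve <- seq_len(16) * 1.0
  curve[c(3, 9)] <- 0
  n_tot <- withr::with_seed(3, {
    replicate(200, sum(add_poisson_noise(curve, 5e4, tg$time_ps)$counts))
  })
  expect_lt(abs(mean(n_tot) - 5e4), 4 * sqrt(5e4))

  d <- add_poisson_noise(curve, 1e5, tg$time_ps, seed = 9)
  expect_identical(d, add_poisson_noise(curve, 1e5, tg$time_ps, seed = 9))
  expect_true(all(d$counts[c(3, 9)] == 0))

  draws <- withr::with_seed(8, {
    replicate(3000, add_poisson_noise(curve, 2e3, tg$time_ps)$counts)
  })
  keep <- curve > 0
  ratio <- apply(draws, 1, stats::var)[keep] / rowMeans(draws)[keep]
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("dead-time loss model: identity at tau 0, exact round trip", {
  cts <- c(100, 5000, 2000); comp <- c(400, 300, 100)
  expect_equal(apply_deadtime(cts, comp, 0), cts)
  expect_equal(correct_deadtime(cts, comp, 0), cts)

  # tau chosen for ~5% counting loss at this rate
  tau <- 0.05 / ((sum(cts) + sum(comp)) / 0.09) * 1e12
  lost <- apply_deadtime(cts, comp, tau)
  expect_lt(sum(lost) / sum(cts), 0.96)
  back <- correct_deadtime(lost, apply_deadtime(comp, cts, tau), tau)
  expect_lt(abs(sum(back) / sum(cts) - 1), 1e-3)

  expect_error(correct_deadtime(cts * 1e9, comp, 1e6), "non-physical")
})

test_that("zero-strength inclusion leaves every expected curve at baseline", {
  ds <- simulate_sweep(
    default_props(), optode_geometry(),
    sweep_grid(x_extent_mm = 8, x_step_mm = 4, y_extent_mm = 1, y_step_mm = 1,
               z_extent_mm = 4, z_step_mm = 4),
    inclusion(dmu_a = 0),
    noise_config(poisson = FALSE, irf_fwhm_ps = 650),
    time_grid(10000, 1024)
  )
  for (nm in ds$channels$name) {
    expect_equal(max(abs(ds$expected[[nm]] - ds$baseline_expected[[nm]])), 0)
  }
})

test_that("homogeneous-medium baselines and mirror positions respect symmetry", {
  ds <- simulate_sweep(
    default_props(), optode_geometry(),
    sweep_grid(x_extent_mm = 12, x_step_mm = 12, y_extent_mm = 1, y_step_mm = 1,
               z_extent_mm = 4, z_step_mm = 4),
    inclusion(),
    noise_config(poisson = FALSE, irf_fwhm_ps = 0),
    time_grid(10000, 1024)
  )
  # far channels (and near channels) share identical baselines
  expect_equal(ds$baseline_expected$left_2, ds$baseline_expected$right_1)
  expect_equal(ds$baseline_expected$left_1, ds$baseline_expected$right_2)
  # inclusion at +/- x: left-source and right-source channels swap curves
  pos <- ds$positions
  i_neg <- which(pos$x_mm == -6 & pos$z_mm == pos$z_mm[1])[1]
  i_pos <- which(pos$x_mm == 6 & pos$z_mm == pos$z_mm[1])[1]
  expect_equal(ds$expected$left_2[, i_neg], ds$expected$right_1[, i_pos],
               tolerance = 1e-12)
  expect_equal(ds$expected$left_1[, i_neg], ds$expected$right_2[, i_pos],
               tolerance = 1e-12)
})

test_that("sweep simulation is bit-reproducible for a fixed seed", {
  args <- list(
    default_props(), optode_geometry(),
    sweep_grid(x_extent_mm = 4, x_step_mm = 4, y_extent_mm = 1, y_step_mm = 1,
               z_extent_mm = 4, z_step_mm = 4),
    inclusion(),
    noise_config(counts_per_dtof = 1e4, n_replicates = 3),
    time_grid(10000, 512)
  )
  d1 <- do.call(simulate_sweep, c(args, seed = 7))
  d2 <- do.call(simulate_sweep, c(args, seed = 7))
  d3 <- do.call(simulate_sweep, c(args, seed = 8))
  expect_identical(d1$dtofs, d2$dtofs)
  expect_false(identical(d1$dtofs, d3$dtofs))
})

test_that("deep inclusions perturb the far channel less in dA but relatively more in V", {
  p <- default_props()
  tg <- time_grid(10000, 2048)
  geo <- optode_geometry()
  ch <- geo$channels[geo$channels$name == "left_2", ]
  base <- reflectance_td(p, 3, tg)
  incl <- inclusion()
  j_shallow <- absorption_jacobian_td(p, c(ch$source_x, 0, 0),
                                      c(ch$detector_x, 0, 0),
                                      c(ch$detector_x, 0, 0.4), tg)
  j_deep <- absorption_jacobian_td(p, c(ch$source_x, 0, 0),
                                   c(ch$detector_x, 0, 0),
                                   c(0, 0, 3.0), tg)
  dm <- function(j) {
    pert <- pmax(base - incl$strength * j, 0)
    delta_moments(moments(dtof(tg$time_ps, base)),
                  moments(dtof(tg$time_ps, pert)))
  }
  d_sh <- dm(j_shallow); d_dp <- dm(j_deep)
  expect_lt(d_dp$dA, d_sh$dA)
  expect_gt(abs(d_dp$dV) / d_dp$dA, abs(d_sh$dV) / d_sh$dA)
})
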