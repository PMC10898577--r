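# hand-built map tibble: one method/moment, values assigned per depth layer
toy_map <- function(values_by_z, z_mm = NULL, method = "sd_far_left",
                    moment = "A") {
  if (is.null(z_mm)) z_mm <- seq_along(values_by_z) * 2 - 1
  tb <- tidyr::expand_grid(x_mm = c(-2, 0, 2), y_mm = 0, z_mm = z_mm)
  tb$i <- seq_len(nrow(tb))
  tb$method <- method
  tb$moment <- moment
  tb$value <- values_by_z[match(tb$z_mm, z_mm)] / 3 # 3 voxels per layer
  structure(tb, class = c("sensitivity_maps", class(tb)))
}

test_that("depth profiles sum layers, preserve sign and are linear", {
  single <- toy_map(c(0, 0, 0, 0, 1, 0, 0, 0))
  pr <- depth_profile(single)
  expect_equal(pr$normalized[pr$z_mm == 9], 1)
  expect_equal(sum(abs(pr$normalized)), 1)

  a <- toy_map(c(1, 0, 0, 0, 0, 0, 0, 0))
  b <- toy_map(c(0, 0, -3, 0, 0, 0, 0, 0))
  ab <- toy_map(c(1, 0, -3, 0, 0, 0, 0, 0))
  pa <- depth_profile(a); pb <- depth_profile(b); pab <- depth_profile(ab)
  expect_equal(pab$layer_sum, pa$layer_sum + pb$layer_sum)
  # normalization divides by the maximal-magnitude layer, keeping sign
  expect_equal(pab$normalized[pab$z_mm == 5], -1)
  expect_equal(pab$normalized[pab$z_mm == 1], 1 / 3)

  expect_warning(depth_profile(toy_map(rep(0, 8))), "all-zero")
})

test_that("depth selectivity is the deep/superficial band ratio with signs", {
  flat <- toy_map(rep(2, 16))
  sel <- depth_selectivity(flat, thickness_layers = 3)
  expect_true(all(abs(sel$S - 1) < 1e-12))
  expect_equal(attr(sel, "thickness_mm"), 6)
  # band starts span the requested 5-30 mm depth range
  expect_true(all(sel$z_start_mm >= 5 & sel$z_start_mm <= 30))

  vals <- c(-2, 0, 0, 4, rep(0, 4))
  m <- toy_map(vals, z_mm = c(2.5, 7.5, 12.5, 17.5, 22.5, 27.5, 32.5, 37.5))
  sel2 <- depth_selectivity(m, thickness_layers = 1,
                            lower_start_range = c(15, 16))
  expect_equal(sel2$S, -2)
})

test_that("theoretical photon-noise sigmas follow the moment error model", {
  bm <- tibble::tibble(
    name = c("left_1", "left_2", "right_1", "right_2"),
    role = c("near", "far", "far", "near"),
    N = 1e6, m1 = 1500, V = 250000, m3 = 0, m4 = 2e11
  )
  nm <- photon_noise_sd(bm)
  g <- function(method, moment) nm$sigma[nm$method == method & nm$moment == moment]
  expect_equal(g("sd_far", "N"), 1000)
  expect_equal(g("sd_far", "A"), 1e-3)
  expect_equal(g("sd_far", "m1"), sqrt(250000 / 1e6))
  expect_equal(g("sd_far", "V"), sqrt((2e11 - 250000^2) / 1e6))
  for (mo in c("N", "A", "m1", "V")) {
    expect_equal(g("ss", mo), sqrt(g("sd_far", mo)^2 + g("sd_near", mo)^2))
    expect_equal(g("ds", mo) / g("ss", mo), 1 / sqrt(2))
  }
  expect_error(photon_noise_sd(dplyr::mutate(bm, N = 0)), "zero total")
})

test_that("empirical Poisson sigmas reproduce the theoretical model", {
  tg <- time_grid(8000, 512)
  curve <- reflectance_td(default_props(), 3, tg)
  d <- truncate_dtof(dtof(tg$time_ps, curve))
  m <- moments(dtof(d$time_ps, d$counts / sum(d$counts) * 1e6))
  emp <- empirical_noise_sd(d$counts, d$time_ps, total_counts = 1e6,
                            n_rep = 4000, seed = 2)
  expect_lt(abs(emp$sigma[emp$moment == "N"] / sqrt(m$N) - 1), 0.05)
  expect_lt(abs(emp$sigma[emp$moment == "m1"] / sqrt(m$V / m$N) - 1), 0.05)
  expect_lt(abs(emp$sigma[emp$moment == "V"] /
                  sqrt((m$m4 - m$V^2) / m$N) - 1), 0.05)
})

test_that("overall performance implements S, CNR and their product", {
  vals <- c(2, 0, 0, 0, 0, 0, 0, 0, 4, 0) # upper sum 2 (z<15), lower sum 4
  m <- toy_map(vals, z_mm = seq(1, 19, by = 2))
  noise <- tibble::tibble(
    method = rep(c("sd_far", "sd_near", "ss", "ds"), each = 1),
    moment = "A", sigma = 1
  )
  perf <- overall_performance(m, noise = noise, top_thickness_mm = 15)
  expect_equal(perf$S, 2)
  expect_equal(perf$CNR, 4)
  expect_equal(perf$performance, 8)
  expect_equal(perf$magnitude, 8)

  noise2 <- dplyr::mutate(noise, sigma = 2)
  perf2 <- overall_performance(m, noise = noise2, top_thickness_mm = 15)
  expect_equal(perf2$S, perf$S)
  expect_equal(perf2$performance, perf$performance / 2)
})

test_that("peak depth extraction uses the maximal-magnitude layer", {
  m <- toy_map(c(0.2, -0.9, 0.5, 0, 0, 0, 0, 0))
  pk <- peak_sensitivity_depth(depth_profile(m))
  expect_equal(pk$z_peak_mm, 3)
})
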