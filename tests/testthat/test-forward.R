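tg_fast <- time_grid(8000, 1024)

test_that("absorption enters all curves only through exp(-mu_a v t)", {
  p <- default_props()
  p0 <- optical_properties(1e-9, 10)
  fac <- exp(-(p$mu_a - p0$mu_a) * p$v * tg_fast$time_ps)

  r <- reflectance_td(p, 3, tg_fast)
  r0 <- reflectance_td(p0, 3, tg_fast, tail_tol = Inf)
  expect_lt(max(abs(r - r0 * fac)) / max(r), 1e-12)

  gf <- greens_fluence(p, c(0, 0, 0.5), c(2, 0, 1), tg_fast)
  gf0 <- greens_fluence(p0, c(0, 0, 0.5), c(2, 0, 1), tg_fast)
  expect_lt(max(abs(gf - gf0 * fac)) / max(gf), 1e-12)

  j <- absorption_jacobian_td(p, c(0, 0, 0), c(3, 0, 0), c(1.5, 0, 1), tg_fast)
  j0 <- absorption_jacobian_td(p0, c(0, 0, 0), c(3, 0, 0), c(1.5, 0, 1), tg_fast)
  expect_lt(max(abs(j - j0 * fac)) / max(j), 1e-10)
})

test_that("total reflectance decreases with separation; grid-too-short errors", {
  p <- default_props()
  r1 <- sum(reflectance_td(p, 2, tg_fast))
  r2 <- sum(reflectance_td(p, 4, tg_fast))
  expect_lt(r2, r1)
  expect_error(reflectance_td(p, 3, time_grid(800, 256)), "grid too short")
})

test_that("fluence kernel is symmetric and vanishes on the extrapolated boundary", {
  p <- default_props()
  a <- c(0.3, -0.2, 0.8); b <- c(2.1, 0.4, 0.2)
  expect_equal(greens_fluence(p, a, b, tg_fast), greens_fluence(p, b, a, tg_fast))
  onb <- greens_fluence(p, a, c(1, 0, -p$zb), tg_fast)
  expect_lt(max(abs(onb)), 1e-9 * max(greens_fluence(p, a, b, tg_fast)))
  expect_error(greens_fluence(p, a, a, tg_fast), "singular")
})

test_that("Jacobian obeys source-detector reciprocity and spatial decay", {
  p <- default_props()
  v <- c(1.2, 0.5, 1.1)
  j1 <- absorption_jacobian_td(p, c(0, 0, 0), c(3, 0, 0), v, tg_fast)
  j2 <- absorption_jacobian_td(p, c(3, 0, 0), c(0, 0, 0), v, tg_fast)
  expect_equal(j1, j2, tolerance = 1e-12)

  near <- absorption_jacobian_td(p, c(0, 0, 0), c(3, 0, 0), c(1.5, 0, 1), tg_fast)
  far <- absorption_jacobian_td(p, c(0, 0, 0), c(3, 0, 0), c(30, 30, 10), tg_fast)
  expect_lt(max(far) / max(near), 1e-6)
  expect_error(
    absorption_jacobian_td(p, c(0, 0, 0), c(3, 0, 0), c(1, 0, -1), tg_fast),
    "inside the medium"
  )
})

test_that("binned reflectance moments agree with the quadrature oracle", {
  p <- default_props()
  tg <- time_grid(10000, 4096)
  r <- reflectance_td(p, 3, tg)
  N <- sum(r)
  m1b <- sum(r * tg$time_ps) / N
  Vb <- sum(r * (tg$time_ps - m1b)^2) / N
  m <- theoretical_moments(p, 3)
  expect_lt(abs(m1b / m$m1 - 1), 1e-4)
  expect_lt(abs(Vb / m$V - 1), 1e-3)
})

test_that("model moments strictly decrease with absorption", {
  mus <- 10
  m_lo <- theoretical_moments(optical_properties(0.05, mus), 3)
  m_mid <- theoretical_moments(optical_properties(0.1, mus), 3)
  m_hi <- theoretical_moments(optical_properties(0.2, mus), 3)
  expect_true(m_lo$m1 > m_mid$m1 && m_mid$m1 > m_hi$m1)
  expect_true(m_lo$V > m_mid$V && m_mid$V > m_hi$V)
})

test_that("convolution adds m1 and V (moment additivity under the IRF)", {
  p <- default_props()
  tg <- time_grid(10000, 2048)
  r <- reflectance_td(p, 3, tg)
  irf <- gaussian_irf(tg, 700)
  rc <- apply_irf(r, irf, tg)
  m_r <- moments(dtof(tg$time_ps, r))
  m_i <- moments(dtof(tg$time_ps, irf))
  m_c <- moments(dtof(tg$time_ps, rc))
  # discrete causal convolution adds mean times up to an exact half-bin
  # offset (index i+j maps to time t_i + t_j + bin/2); variances add exactly
  expect_lt(abs(m_c$m1 - m_r$m1 - m_i$m1 + tg$bin_width / 2), 0.1)
  expect_lt(abs((m_c$V - m_r$V - m_i$V) / m_c$V), 1e-4)
})

test_that("optical properties are recovered from noiseless moments", {
  p <- optical_properties(0.098, 10.13)
  tg <- time_grid(10000, 4096)
  r <- reflectance_td(p, 3, tg)

  m <- moments(dtof(tg$time_ps, r))
  fit <- estimate_optical_properties(m, rho = 3)
  expect_lt(abs(fit$props$mu_a / p$mu_a - 1), 0.02)
  expect_lt(abs(fit$props$mu_s_prime / p$mu_s_prime - 1), 0.02)

  irf <- gaussian_irf(tg, 650)
  m_conv <- moments(dtof(tg$time_ps, apply_irf(r, irf, tg)))
  m_irf <- moments(dtof(tg$time_ps, irf))
  fit2 <- estimate_optical_properties(m_conv, irf = m_irf, rho = 3)
  expect_lt(abs(fit2$props$mu_a / p$mu_a - 1), 0.02)
  expect_lt(abs(fit2$props$mu_s_prime / p$mu_s_prime - 1), 0.02)

  td <- tidy(fit)
  expect_equal(td$term, c("mu_a", "mu_s_prime"))
  expect_true(glance(fit)$converged)

  expect_error(
    estimate_optical_properties(
      tibble::tibble(N = 1, m1 = 500, V = 100),
      irf = tibble::tibble(N = 1, m1 = 100, V = 200), rho = 3
    ),
    "variance"
  )
})

test_that("recovery stays accurate under Poisson noise", {
  p <- optical_properties(0.098, 10.13)
  tg <- time_grid(10000, 2048)
  lam <- reflectance_td(p, 3, tg)
  lam <- lam / sum(lam) * 1e6
  errs <- withr::with_seed(5, {
    replicate(20, {
      m <- moments(dtof(tg$time_ps, stats::rpois(length(lam), lam)))
      f <- estimate_optical_properties(m, rho = 3)
      c(abs(f$props$mu_a / p$mu_a - 1), abs(f$props$mu_s_prime / p$mu_s_prime - 1))
    })
  })
  expect_lt(max(errs[1, ]), 0.05)
  expect_lt(max(errs[2, ]), 0.10)
})
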