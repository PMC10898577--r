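test_that("truncation cuts at the first sub-threshold bin on each side", {
  d <- dtof(c(10, 20, 30, 40, 50), c(1, 5, 100, 50, 0.5))
  tr <- truncate_dtof(d)
  expect_equal(tr$counts, c(1, 5, 100, 50))

  # a bin exactly at the threshold is retained
  d2 <- dtof(1:5 * 10, c(1, 5, 100, 50, 1))
  expect_equal(nrow(truncate_dtof(d2)), 5)

  # constant histogram is returned unchanged
  d3 <- dtof(1:6 * 10, rep(7, 6))
  expect_equal(truncate_dtof(d3)$counts, rep(7, 6))

  # noise re-crossings beyond the first cut do not re-extend the window
  d4 <- dtof(1:7 * 10, c(0.5, 2, 100, 60, 0.5, 30, 0.5))
  expect_equal(truncate_dtof(d4)$counts, c(2, 100, 60))

  expect_error(truncate_dtof(dtof(1:3, c(0, 0, 0))), "empty")
  expect_error(truncate_dtof(dtof(1:3, c(0, 1, 0)), threshold_fraction = 1))
})

test_that("truncation of a Gaussian retains the analytic 1% support", {
  sigma <- 300; bw <- 2
  d <- gaussian_dtof(sigma = sigma, bw = bw)
  tr <- truncate_dtof(d, 0.01)
  half_width <- (max(tr$time_ps) - min(tr$time_ps)) / 2
  expect_lt(abs(half_width - sqrt(2 * log(100)) * sigma), bw + 1e-9)
})

test_that("moments match closed forms on degenerate and Gaussian shapes", {
  d1 <- dtof(1000, 1000)
  m1 <- moments(d1)
  expect_equal(as.numeric(m1), c(1000, 1000, 0, 0, 0))

  d2 <- dtof(c(1000, 2000), c(500, 500))
  m2 <- moments(d2)
  expect_equal(m2$m1, 1500)
  expect_equal(m2$V, 250000)
  expect_equal(m2$m3, 0)

  mg <- moments(gaussian_dtof(sigma = 300))
  expect_lt(abs(mg$V / 9e4 - 1), 0.01)
  expect_lt(abs(mg$m4 / mg$V^2 - 3), 0.02 * 3)

  expect_error(moments(dtof(1:3, c(0, 0, 0))), "zero total")
})

test_that("moment computation is scale-invariant and shift-equivariant", {
  d <- gaussian_dtof(sigma = 250, bw = 5)
  m <- moments(d)
  ms <- moments(dtof(d$time_ps, d$counts * 7.3))
  expect_equal(ms$N, m$N * 7.3)
  expect_equal(ms[c("m1", "V", "m3", "m4")], m[c("m1", "V", "m3", "m4")])

  msh <- moments(dtof(d$time_ps + 123, d$counts))
  expect_equal(msh$m1, m$m1 + 123)
  expect_equal(msh$V, m$V)
  expect_equal(msh$m4, m$m4)
  # m3 of a symmetric shape is ~0; compare on the natural V^(3/2) scale
  expect_lt(abs(msh$m3 - m$m3) / m$V^1.5, 1e-10)
})

test_that("truncation is idempotent and never increases total counts", {
  set.seed(7)
  for (k in 1:20) {
    cts <- stats::rpois(200, 50 * exp(-abs(seq(-3, 3, length.out = 200))))
    if (max(cts) == 0) next
    d <- dtof(seq_len(200) * 5, cts)
    t1 <- truncate_dtof(d)
    t2 <- truncate_dtof(t1)
    expect_identical(t1$counts, t2$counts)
    expect_lte(sum(t1$counts), sum(d$counts))
  }
})

test_that("averaging DTOFs is idempotent, linear, and reduces Poisson variance", {
  d <- gaussian_dtof(bw = 10)
  expect_equal(average_dtofs(list(d, d, d))$counts, d$counts)

  z <- dtof(1:5 * 10, rep(0, 5)); two <- dtof(1:5 * 10, rep(2, 5))
  expect_equal(average_dtofs(list(z, two))$counts, rep(1, 5))

  expect_error(average_dtofs(list(d, dtof(d$time_ps + 1, d$counts))), "grid")

  # variance of a 10-fold average is ~1/10 of the single-shot variance
  lam <- c(40, 80, 120)
  t <- c(10, 20, 30)
  set.seed(11)
  single <- replicate(2000, stats::rpois(3, lam))
  avg <- replicate(2000, {
    reps <- lapply(1:10, function(i) dtof(t, stats::rpois(3, lam)))
    average_dtofs(reps)$counts
  })
  ratio <- apply(avg, 1, stats::var) / apply(single, 1, stats::var)
  expect_true(all(abs(ratio * 10 - 1) < 0.15))
})
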