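test_that("the strand densities are proper, mirrored, and match the convolution oracle", {
  sh <- global_shape(40, 60)

  ## normalization across a grid of shapes, by trapezoid quadrature
  for (sigma in c(10, 40, 80)) for (beta in c(20, 60, 120)) {
    s <- global_shape(sigma, beta)
    x <- seq(-20 * sigma, 20 * (sigma + beta), by = 0.1)
    fr <- density_right(x, mu = 0, shape = s)
    fl <- density_left(-x, mu = 0, shape = s)   # mass mirrored upstream
    expect_equal(sum((fr[-1] + fr[-length(fr)]) / 2) * 0.1, 1,
                 tolerance = 1e-6)
    expect_equal(sum((fl[-1] + fl[-length(fl)]) / 2) * 0.1, 1,
                 tolerance = 1e-6)
  }

  ## closed form against direct numeric convolution
  set.seed(5)
  x <- sort(c(0, runif(49, -300, 500)))
  expect_equal(density_right(x, mu = 0, shape = sh),
               quad_density_right(x, 0, 40, 60), tolerance = 1e-9)

  ## mirror identity f_L(mu - z) = f_R(mu + z)
  z <- -500:500
  expect_equal(density_left(100 - z, mu = 100, shape = sh),
               density_right(100 + z, mu = 100, shape = sh),
               tolerance = 1e-12)
  zfine <- seq(-50, 50, by = 0.25)
  modeL <- max(density_left(zfine, 0, sh))
  modeR <- max(density_right(zfine, 0, sh))
  expect_equal(modeL, modeR, tolerance = 1e-12)
})

test_that("the left tail vanishes fast and the log-space form never overflows", {
  sh <- global_shape(40, 60)
  expect_lt(density_right(-10 * 40, mu = 0, shape = sh), 1e-12)
  far <- density_right(-1e4 * sh$beta, mu = 0, shape = sh)
  expect_true(is.finite(far))
  expect_gte(far, 0)
  expect_true(all(is.finite(density_right(seq(-6e5, 6e5, length.out = 101),
                                          mu = 0, shape = sh))))
  expect_error(density_right(NaN, 0, sh), "finite")
  expect_error(density_left(0, Inf, sh), "finite")
})

test_that("the Poisson intensity adds background to the scaled density", {
  sh <- global_shape(40, 60)
  pos <- 1:500

  p0 <- region_params(mu = 250, nu = 0, rho = 0.3)
  expect_equal(intensity(pos, "left", p0, sh), rep(0.3, 500))
  expect_equal(intensity(pos, "right", p0, sh), rep(0.3, 500))

  ## integrating out the background recovers nu (consistency check)
  p <- region_params(mu = 0, nu = 150, rho = 0.05)
  x <- seq(-20 * (40 + 60), 20 * (40 + 60))
  expect_equal(sum(intensity(x, "right", p, sh) - p$rho), 150,
               tolerance = 150 * 1e-3)

  ## mirror symmetry with shared (nu, rho)
  z <- -200:200
  expect_equal(intensity(250 - z, "left", region_params(250, 80, 0.1), sh),
               intensity(250 + z, "right", region_params(250, 80, 0.1), sh))
})

test_that("the region log-likelihood censors unmappable positions correctly", {
  sh <- global_shape(40, 60)
  p <- region_params(mu = 3, nu = 5, rho = 0.2)

  ## fully censored region contributes nothing
  all_masked <- region_tags(rep(0, 4), rep(0, 4),
                            unmappable_left = rep(TRUE, 4),
                            unmappable_right = rep(TRUE, 4))
  expect_identical(region_log_likelihood(all_masked, p, sh), 0)

  ## 5-bp region assembled by hand from the Poisson log pmf
  yl <- c(0, 1, 2, 0, 1); yr <- c(1, 0, 0, 3, 0)
  tg <- region_tags(yl, yr)
  lamL <- p$nu * density_left(1:5, p$mu, sh) + p$rho
  lamR <- p$nu * density_right(1:5, p$mu, sh) + p$rho
  by_hand <- sum(yl * log(lamL) - lamL - lfactorial(yl)) +
    sum(yr * log(lamR) - lamR - lfactorial(yr))
  expect_equal(region_log_likelihood(tg, p, sh), by_hand,
               tolerance = 1e-12)

  ## masking a zero-count position removes exactly its two e^{-lambda} terms
  masked <- region_tags(yl, yr,
                        unmappable_left = c(F, F, F, T, F),
                        unmappable_right = c(F, F, T, F, F))
  expect_equal(region_log_likelihood(masked, p, sh),
               by_hand + lamL[4] + lamR[3], tolerance = 1e-12)

  ## translation of all coordinates leaves the likelihood unchanged
  shifted <- region_tags(yl, yr, start = 10001)
  pshift <- region_params(mu = 10003, nu = 5, rho = 0.2)
  expect_equal(region_log_likelihood(shifted, pshift, sh), by_hand,
               tolerance = 1e-10)
})

test_that("constructors reject inconsistent inputs", {
  expect_error(global_shape(-1, 50), "positive")
  expect_error(global_shape(30, 0), "positive")
  expect_error(region_params(0, -1, 0.1), "non-negative")
  expect_error(region_params(0, 1, 0), "positive")
  expect_error(region_tags(c(0, 1), c(0, 0, 0)), "same length")
  expect_error(region_tags(c(0, -1), c(0, 0)), "non-negative")
  expect_error(region_tags(c(0, 1.5), c(0, 0)), "integers")
  expect_error(region_tags(c(0, 1), c(0, 0),
                           unmappable_left = c(FALSE, TRUE)),
               "unmappable")
})
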