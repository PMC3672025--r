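sh40 <- global_shape(40, 60)

test_that("the null fit has its closed form and is always nested", {
  tg <- region_tags(rep(1, 100), rep(1, 100))
  n0 <- fit_null(tg)
  expect_equal(n0$rho, 1.0)

  tg2 <- region_tags(c(rep(1, 20), rep(0, 55)),
                     c(rep(1, 10), rep(0, 65)))
  expect_equal(fit_null(tg2)$rho, 0.2)

  expect_error(fit_null(region_tags(0, 0, unmappable_left = TRUE,
                                    unmappable_right = TRUE)),
               "mappable")

  ## nesting: the unrestricted fit never falls below the null fit
  set.seed(401)
  for (i in 1:100) {
    tg <- random_region_fixture(120, mu = runif(1, 20, 100),
                                nu = runif(1, 0, 60),
                                rho = runif(1, 0.02, 0.5), sh40)
    f <- fit_region(tg, sh40)
    expect_gte(f$loglik, f$null_loglik - 1e-8)
    expect_gte(f$lr_stat, 0)
  }
})

test_that("a flat background yields a boundary fit with the right background level", {
  set.seed(402)
  tg <- random_region_fixture(500, mu = 250, nu = 0, rho = 0.2, sh40)
  f <- fit_region(tg, sh40)
  expect_lt(f$params_hat$nu, 8)           # at or near the nu = 0 boundary
  se_rho <- sqrt(0.2 / 1000)              # Poisson MLE SE over 2x500 slots
  expect_lt(abs(f$params_hat$rho - 0.2), 3 * se_rho + f$params_hat$nu / 500)
})

test_that("an all-zero region returns the documented degenerate fit", {
  tg <- region_tags(rep(0, 60), rep(0, 60))
  f <- fit_region(tg, sh40)
  expect_equal(f$params_hat$nu, 0)
  expect_equal(f$lr_stat, 0)
  expect_equal(f$lr_pvalue, 1)
  expect_true(f$converged)
})

test_that("fits are equivariant under translation of the region", {
  set.seed(403)
  lamL <- 120 * density_left(1:400, 180, sh40) + 0.15
  lamR <- 120 * density_right(1:400, 180, sh40) + 0.15
  yl <- rpois(400, lamL); yr <- rpois(400, lamR)
  f1 <- fit_region(region_tags(yl, yr, start = 1), sh40)
  f2 <- fit_region(region_tags(yl, yr, start = 70001), sh40)
  expect_equal(f2$params_hat$mu - f1$params_hat$mu, 70000,
               tolerance = 1e-3)
  expect_equal(f2$params_hat$nu, f1$params_hat$nu, tolerance = 1e-4)
  expect_equal(f2$params_hat$rho, f1$params_hat$rho, tolerance = 1e-6)
  expect_equal(f2$lr_stat, f1$lr_stat, tolerance = 1e-5)
  expect_equal(f2$gof_stat, f1$gof_stat, tolerance = 1e-5)
})

test_that("the binding LR test matches the chi-square reference", {
  set.seed(404)
  tg <- random_region_fixture(300, 150, 100, 0.1, sh40)
  f <- fit_region(tg, sh40)
  t1 <- binding_lr_test(f)
  expect_equal(t1$lr_stat, f$lr_stat)
  expect_equal(t1$pvalue, pchisq(f$lr_stat, 1, lower.tail = FALSE))

  ## identical likelihoods -> lambda = 0, p = 1
  f0 <- f; f0$loglik <- f0$null_loglik
  t0 <- binding_lr_test(f0)
  expect_equal(t0$lr_stat, 0)
  expect_equal(t0$pvalue, 1)

  ## the 95% quantile of chi-square(1)
  f95 <- f; f95$loglik <- f95$null_loglik + 3.841459 / 2
  expect_equal(binding_lr_test(f95)$pvalue, 0.05, tolerance = 1e-6)
})

test_that("the goodness-of-fit statistic is the Poisson deviance on mappable slots", {
  sh <- sh40

  ## counts equal to the fitted intensities exactly -> zero deviance
  flat <- region_params(mu = 10, nu = 0, rho = 2)
  tg0 <- region_tags(rep(2, 50), rep(2, 50))
  g0 <- goodness_of_fit_test(tg0, flat, sh)
  expect_equal(g0$gof_stat, 0, tolerance = 1e-10)
  expect_equal(g0$pvalue, 1)
  expect_equal(g0$df, 97L)

  ## deviance identity against the formula assembled by hand, masked case
  set.seed(405)
  tg <- random_region_fixture(80, 40, 50, 0.2, sh)
  umL <- rep(c(TRUE, FALSE), 40)
  cl <- tg$counts_left; cl[umL] <- 0
  tgm <- region_tags(cl, tg$counts_right, unmappable_left = umL)
  p <- region_params(mu = 40, nu = 50, rho = 0.2)
  g <- goodness_of_fit_test(tgm, p, sh)
  y <- c(cl[!umL], tg$counts_right)
  lam <- c(intensity((1:80)[!umL], "left", p, sh),
           intensity(1:80, "right", p, sh))
  dev <- 2 * sum(ifelse(y > 0, y * log(y / lam), 0) - (y - lam))
  expect_equal(g$gof_stat, dev, tolerance = 1e-10)
  expect_equal(g$df, length(y) - 3L)

  ## too few mappable slots -> undefined test, missing p
  tiny <- region_tags(c(1, 0), c(0, 1), unmappable_left = c(FALSE, TRUE))
  gt <- goodness_of_fit_test(tiny, region_params(1, 0, 0.5), sh)
  expect_false(gt$defined)
  expect_true(is.na(gt$pvalue))
})

test_that("standard errors are calibrated and shrink with tag depth", {
  set.seed(406)
  tg <- random_region_fixture(500, 250, 200, 0.1, sh40)
  f <- fit_region(tg, sh40)
  expect_true(f$se_ok)
  expect_equal(f$covariance, t(f$covariance), tolerance = 1e-8)
  expect_true(all(diag(f$covariance) > 0))
  se <- standard_errors(f)
  expect_equal(se$se_mu, sqrt(f$covariance[1, 1]))

  ## empirical SD of mu-hat against the mean reported SE (300 replicates)
  set.seed(407)
  res <- replicate(300, {
    f <- fit_region(random_region_fixture(500, 250, 200, 0.1, sh40), sh40)
    c(f$params_hat$mu, f$se_mu)
  })
  expect_lt(abs(sd(res[1, ]) - mean(res[2, ], na.rm = TRUE)),
            0.2 * mean(res[2, ], na.rm = TRUE))

  ## location accuracy improves with depth
  set.seed(408)
  se_low <- mean(replicate(25, fit_region(
    random_region_fixture(500, 250, 100, 0.1, sh40), sh40)$se_mu),
    na.rm = TRUE)
  se_high <- mean(replicate(25, fit_region(
    random_region_fixture(500, 250, 800, 0.1, sh40), sh40)$se_mu),
    na.rm = TRUE)
  expect_lt(se_high, se_low)
})

test_that("global shape training recovers (sigma, beta) from anchored regions", {
  expect_equal(fit_global(list(), numeric()), global_shape(30, 50))

  set.seed(409)
  truth <- global_shape(40, 60)
  training <- lapply(1:50, function(i)
    random_region_fixture(500, 250, 300, 0.1, truth))
  est <- fit_global(training, rep(250, 50))
  expect_lt(abs(est$sigma - 40) / 40, 0.10)
  expect_lt(abs(est$beta - 60) / 60, 0.10)

  ## the profiled objective prefers the truth over an inflated shape,
  ## assembled independently of fit_global
  profiled <- function(shape) {
    sum(vapply(training, function(tg) {
      obj <- function(p) -region_log_likelihood(
        tg, region_params(250, p[1], p[2]), shape)
      -optim(c(250, 0.1), obj, method = "L-BFGS-B",
             lower = c(0, 1e-9))$value
    }, 0))
  }
  expect_gt(profiled(truth), profiled(global_shape(60, 90)))
})
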