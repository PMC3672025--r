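## Per-region maximum likelihood, standard errors, binding LR test,
## goodness-of-fit test, and global (sigma, beta) training.

## fitted-parameter constructor that skips user-input validation (a fitted
## rho can sit at the numerical lower bound, or at 0 for an empty region)
new_region_params <- function(mu, nu, rho) {
  structure(list(mu = as.numeric(mu), nu = as.numeric(nu),
                 rho = as.numeric(rho)), class = "RegionParams")
}

## negative log-likelihood and analytic gradient in theta = (mu, nu, rho)
region_negll <- function(par, tags, shape, pos, mL, mR, yL, yR) {
  mu <- par[1]; nu <- par[2]; rho <- par[3]
  fL <- exp(emg_log_density(mu - pos[mL], shape$sigma, shape$beta))
  fR <- exp(emg_log_density(pos[mR] - mu, shape$sigma, shape$beta))
  lamL <- nu * fL + rho
  lamR <- nu * fR + rho
  -(sum(stats::dpois(yL, lamL, log = TRUE)) +
      sum(stats::dpois(yR, lamR, log = TRUE)))
}

region_negll_grad <- function(par, tags, shape, pos, mL, mR, yL, yR) {
  mu <- par[1]; nu <- par[2]; rho <- par[3]
  tL <- mu - pos[mL]
  tR <- pos[mR] - mu
  fL <- exp(emg_log_density(tL, shape$sigma, shape$beta))
  fR <- exp(emg_log_density(tR, shape$sigma, shape$beta))
  lamL <- nu * fL + rho
  lamR <- nu * fR + rho
  rL <- yL / lamL - 1          # d loglik / d lambda
  rR <- yR / lamR - 1
  dL <- emg_density_deriv(tL, shape$sigma, shape$beta)
  dR <- emg_density_deriv(tR, shape$sigma, shape$beta)
  g_mu  <- sum(rL * nu * dL) - sum(rR * nu * dR)
  g_nu  <- sum(rL * fL) + sum(rR * fR)
  g_rho <- sum(rL) + sum(rR)
  -c(g_mu, g_nu, g_rho)
}

## deterministic starting values: mu0 from the midpoint of the smoothed
## strand modes, rho0 from the lower quartile of counts (robust to the
## peak), nu0 from the excess of tags over background
default_init <- function(tags) {
  pos <- region_positions(tags)
  smooth_mode <- function(cnt) {
    if (sum(cnt) == 0) return(stats::median(pos))
    sm <- as.numeric(stats::filter(cnt, rep(1 / 21, 21), sides = 2))
    sm[is.na(sm)] <- -1
    pos[which.max(sm)]
  }
  modeL <- smooth_mode(tags$counts_left)
  modeR <- smooth_mode(tags$counts_right)
  mu0 <- (modeL + modeR) / 2
  cnt <- c(tags$counts_left[!tags$unmappable_left],
           tags$counts_right[!tags$unmappable_right])
  rho0 <- max(stats::quantile(cnt, 0.25, names = FALSE), 1e-3)
  nu0 <- max(total_tags(tags) - tags$width * rho0 * 2, 1) / 2
  new_region_params(mu0, nu0, rho0)
}

#' Background-only (null) fit of a region
#'
#' Under the no-binding restriction `nu = 0` the binding location is
#' unidentifiable and the constant-intensity Poisson MLE has the closed form
#' `rho = (total mappable tags on both strands) / (number of mappable
#' position-strand pairs)`.
#'
#' @param tags A [region_tags()] object with at least one mappable position.
#' @return A list with `rho` (the restricted MLE) and `loglik`.
#' @export
fit_null <- function(tags) {
  stopifnot(inherits(tags, "RegionTags"))
  nm <- n_mappable(tags)
  if (nm == 0L) stop("region has no mappable positions")
  rho <- total_tags(tags) / nm
  yL <- tags$counts_left[!tags$unmappable_left]
  yR <- tags$counts_right[!tags$unmappable_right]
  ll <- sum(stats::dpois(c(yL, yR), rho, log = TRUE))
  list(rho = rho, loglik = ll)
}

## central-difference Hessian of the log-likelihood at theta_hat
observed_information <- function(fn, par, steps) {
  k <- length(par)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(par)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, steps[i])
    H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / steps[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, steps[j])
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) /
        (4 * steps[i] * steps[j])
    }
  }
  H
}

#' Fit the two-peak model to one region
#'
#' Maximizes the region log-likelihood over `(mu, nu >= 0, rho > 0)` with
#' the global shape `(sigma, beta)` held fixed, by bounded quasi-Newton
#' (L-BFGS-B) with analytic gradients. The no-binding profile (`nu = 0`,
#' [fit_null()]) is always evaluated as well, so a boundary optimum is never
#' missed. The asymptotic covariance is the inverse observed information
#' (negative Hessian of the log-likelihood at the optimum, by central
#' finite differences); the binding likelihood-ratio test and the
#' goodness-of-fit test are filled in.
#'
#' @param tags A [region_tags()] object.
#' @param shape A [global_shape()] object.
#' @param init Optional [region_params()] starting values; the default is a
#'   deterministic data-driven initialization.
#' @return An object of class `"RegionFit"`; see Details. Key fields:
#'   `params_hat` (`mu`, `nu`, `rho` estimates), `covariance`, `se_mu`,
#'   `se_nu`, `se_rho`, `loglik`, `null_loglik`, `lr_stat`, `lr_pvalue`,
#'   `gof_stat`, `gof_df`, `gof_pvalue`, `converged`.
#' @examples
#' sh <- global_shape(40, 60)
#' set.seed(1)
#' tg <- simulate_region(width = 500, shape = sh, mu = 250, nu = 150,
#'                       rho = 0.1)
#' fit_region(tg, sh)
#' @export
fit_region <- function(tags, shape, init = NULL) {
  stopifnot(inherits(tags, "RegionTags"), inherits(shape, "GlobalShape"))
  null <- fit_null(tags)
  w <- tags$width
  pos <- region_positions(tags)
  mL <- !tags$unmappable_left
  mR <- !tags$unmappable_right
  yL <- tags$counts_left[mL]
  yR <- tags$counts_right[mR]

  if (total_tags(tags) == 0) {
    fit <- build_region_fit(tags, shape,
                            new_region_params(tags$start + (w - 1) / 2, 0,
                                              null$rho),
                            loglik = null$loglik, null = null,
                            converged = TRUE, opt = NULL)
    return(fit)
  }

  if (is.null(init)) init <- default_init(tags)
  par0 <- c(init$mu, init$nu, max(init$rho, 1e-9))
  lower <- c(tags$start - w, 0, 1e-9)
  upper <- c(tags$start + 2 * w, Inf, Inf)
  opt <- stats::optim(par0, region_negll, region_negll_grad,
                      tags = tags, shape = shape, pos = pos,
                      mL = mL, mR = mR, yL = yL, yR = yR,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = 1e7, maxit = 500))
  ll <- -opt$value
  converged <- opt$convergence == 0L
  params <- new_region_params(opt$par[1], opt$par[2], opt$par[3])
  if (null$loglik >= ll) {
    ## the boundary nu = 0 profile dominates the interior search
    params <- new_region_params(init$mu, 0, null$rho)
    ll <- null$loglik
    converged <- TRUE
  }
  build_region_fit(tags, shape, params, loglik = ll, null = null,
                   converged = converged, opt = opt)
}

build_region_fit <- function(tags, shape, params, loglik, null, converged,
                             opt) {
  lr <- max(0, 2 * (loglik - null$loglik))
  gof <- goodness_of_fit_test(tags, params, shape)
  fit <- structure(list(
    params_hat = params,
    covariance = NULL,
    se_mu = NA_real_, se_nu = NA_real_, se_rho = NA_real_,
    se_ok = FALSE,
    loglik = loglik, null_loglik = null$loglik, null_rho = null$rho,
    lr_stat = lr,
    lr_pvalue = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    gof_stat = gof$gof_stat, gof_df = gof$df, gof_pvalue = gof$pvalue,
    gof_defined = gof$defined,
    converged = converged,
    start = tags$start, width = tags$width,
    n_mappable = n_mappable(tags), n_tags = total_tags(tags),
    shape = shape), class = "RegionFit")
  if (converged && params$nu > 1e-6 && params$rho > 1e-8) {
    pos <- region_positions(tags)
    mL <- !tags$unmappable_left
    mR <- !tags$unmappable_right
    yL <- tags$counts_left[mL]
    yR <- tags$counts_right[mR]
    llfun <- function(p) -region_negll(p, tags, shape, pos, mL, mR, yL, yR)
    steps <- c(0.01, min(0.1, params$nu / 2), min(1e-4, params$rho / 2))
    H <- observed_information(llfun, c(params$mu, params$nu, params$rho),
                              steps)
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
      V <- (V + t(V)) / 2
      fit$covariance <- V
      fit$se_mu <- sqrt(V[1, 1])
      fit$se_nu <- sqrt(V[2, 2])
      fit$se_rho <- sqrt(V[3, 3])
      fit$se_ok <- TRUE
    }
  }
  fit
}

#' @export
print.RegionFit <- function(x, ...) {
  p <- x$params_hat
  cat(sprintf("RegionFit [%d, %d]:\n", as.integer(x$start),
              as.integer(x$start + x$width - 1)))
  cat(sprintf("  mu = %.2f (SE %.2f), nu = %.2f (SE %.2f), rho = %.4f\n",
              p$mu, x$se_mu, p$nu, x$se_nu, p$rho))
  cat(sprintf("  binding LR = %.2f (p = %.3g); GOF = %.2f on %d df (p = %.3g)\n",
              x$lr_stat, x$lr_pvalue, x$gof_stat, x$gof_df,
              if (x$gof_defined) x$gof_pvalue else NA))
  if (!x$converged) cat("  [optimizer did not converge]\n")
  invisible(x)
}

#' Likelihood-ratio test for the presence of binding
#'
#' Compares the fitted model against the no-binding restriction `nu = 0`:
#' `lambda = -2 log(L(null)/L(fitted))`, referred to the chi-square
#' distribution with 1 degree of freedom. The `nu >= 0` boundary makes the
#' reference distribution conservative. The statistic is clipped at 0.
#'
#' @param fit A `"RegionFit"` from [fit_region()].
#' @return A list with `lr_stat` and `pvalue`.
#' @export
binding_lr_test <- function(fit) {
  stopifnot(inherits(fit, "RegionFit"))
  lr <- max(0, 2 * (fit$loglik - fit$null_loglik))
  list(lr_stat = lr,
       pvalue = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Goodness-of-fit test of the two-peak model in a region
#'
#' Likelihood-ratio test of the fitted model against the saturated Poisson
#' alternative with one free intensity per mappable position per strand
#' (whose MLE is the observed count). The statistic reduces to the Poisson
#' deviance `2 * sum(y*log(y/lambda0) - (y - lambda0))` (with
#' `0*log(0) = 0`) against the fitted intensities, on
#' `(mappable position-strand pairs) - 3` degrees of freedom. Small
#' p-values flag regions the model describes poorly: PCR spikes in short
#' regions, multiple binding events in long ones.
#'
#' @param tags A [region_tags()] object.
#' @param fit A `"RegionFit"` or `"RegionParams"` giving the null (fitted
#'   model) intensities.
#' @param shape A [global_shape()] object; defaults to the shape stored in
#'   `fit` when available.
#' @return A list with `gof_stat`, `df`, `pvalue` and `defined` (`FALSE`
#'   with `pvalue = NA` when `df <= 0`).
#' @export
goodness_of_fit_test <- function(tags, fit, shape = NULL) {
  stopifnot(inherits(tags, "RegionTags"))
  if (inherits(fit, "RegionFit")) {
    if (is.null(shape)) shape <- fit$shape
    params <- fit$params_hat
  } else params <- fit
  stopifnot(inherits(params, "RegionParams"), inherits(shape, "GlobalShape"))
  pos <- region_positions(tags)
  mL <- !tags$unmappable_left
  mR <- !tags$unmappable_right
  y <- c(tags$counts_left[mL], tags$counts_right[mR])
  lam <- c(intensity(pos[mL], "left", params, shape),
           intensity(pos[mR], "right", params, shape))
  dev_terms <- -(y - lam)
  nz <- y > 0
  dev_terms[nz] <- dev_terms[nz] + y[nz] * log(y[nz] / lam[nz])
  stat <- 2 * sum(dev_terms)
  df <- length(y) - 3L
  if (df <= 0L)
    return(list(gof_stat = stat, df = df, pvalue = NA_real_,
                defined = FALSE))
  list(gof_stat = stat, df = df,
       pvalue = stats::pchisq(stat, df = df, lower.tail = FALSE),
       defined = TRUE)
}

#' Asymptotic standard errors of a region fit
#'
#' Square roots of the diagonal of the inverse observed information
#' (negative Hessian of the log-likelihood at the optimum). Missing (with
#' `ok = FALSE`) when the fit did not converge, sits on the `nu = 0`
#' boundary, or the information matrix is singular or indefinite.
#'
#' @param fit A `"RegionFit"`.
#' @return A list with `se_mu`, `se_nu`, `se_rho` and `ok`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "RegionFit"))
  list(se_mu = fit$se_mu, se_nu = fit$se_nu, se_rho = fit$se_rho,
       ok = fit$se_ok)
}

## profile (nu, rho) at fixed mu and shape; returns the maximized loglik
profile_nu_rho <- function(yL, yR, fL, fR, nu0, rho0) {
  negll <- function(p) {
    lamL <- p[1] * fL + p[2]
    lamR <- p[1] * fR + p[2]
    -(sum(stats::dpois(yL, lamL, log = TRUE)) +
        sum(stats::dpois(yR, lamR, log = TRUE)))
  }
  grad <- function(p) {
    lamL <- p[1] * fL + p[2]
    lamR <- p[1] * fR + p[2]
    rL <- yL / lamL - 1
    rR <- yR / lamR - 1
    -c(sum(rL * fL) + sum(rR * fR), sum(rL) + sum(rR))
  }
  opt <- stats::optim(c(nu0, rho0), negll, grad, method = "L-BFGS-B",
                      lower = c(0, 1e-9), upper = c(Inf, Inf),
                      control = list(factr = 1e7, maxit = 200))
  -opt$value
}

#' Train the global shape parameters on anchored regions
#'
#' Estimates `(sigma, beta)` by maximizing the summed region log-likelihood
#' over a training set in which each region's binding location `mu` is held
#' fixed at an external anchor (typically a motif-site center found by
#' [scan_sequence()]), while each region's `(nu, rho)` are profiled out at
#' their inner optima. With no training data the documented defaults
#' `sigma = 30`, `beta = 50` are returned.
#'
#' @param training A list of [region_tags()] objects.
#' @param anchors Numeric vector of anchor coordinates (one per region,
#'   genomic scale).
#' @param init A [global_shape()] starting point (also the default returned
#'   for an empty training set).
#' @return A [global_shape()] object with the fitted `(sigma, beta)`.
#' @export
fit_global <- function(training, anchors, init = global_shape(30, 50)) {
  stopifnot(is.list(training), length(training) == length(anchors))
  if (length(training) == 0L) return(init)
  prep <- lapply(seq_along(training), function(i) {
    tg <- training[[i]]
    stopifnot(inherits(tg, "RegionTags"))
    pos <- region_positions(tg)
    mL <- !tg$unmappable_left
    mR <- !tg$unmappable_right
    ini <- default_init(tg)
    list(posL = pos[mL], posR = pos[mR],
         yL = tg$counts_left[mL], yR = tg$counts_right[mR],
         mu = anchors[i], nu0 = ini$nu, rho0 = ini$rho)
  })
  negll <- function(lp) {
    sigma <- exp(lp[1]); beta <- exp(lp[2])
    tot <- 0
    for (p in prep) {
      fL <- exp(emg_log_density(p$mu - p$posL, sigma, beta))
      fR <- exp(emg_log_density(p$posR - p$mu, sigma, beta))
      tot <- tot + profile_nu_rho(p$yL, p$yR, fL, fR, p$nu0, p$rho0)
    }
    -tot
  }
  opt <- stats::optim(log(c(init$sigma, init$beta)), negll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-7, maxit = 300))
  global_shape(exp(opt$par[1]), exp(opt$par[2]))
}
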