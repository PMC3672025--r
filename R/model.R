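#' Global tag-shape parameters
#'
#' The two genome-wide parameters of the normal-exponential two-peak model:
#' `sigma`, the standard deviation (bp) of the cross-link position around the
#' binding-site center, and `beta`, the mean (bp) of the exponential distance
#' from the cross-link to the nearer fragment end. They are shared by every
#' candidate region; per-region parameters live in [region_params()].
#'
#' The defaults (`sigma = 30`, `beta = 50`) are the documented fallback used
#' when no motif-anchored training data are available; [fit_global()]
#' estimates both from training regions.
#'
#' @param sigma Cross-link standard deviation in bp; must be positive.
#' @param beta Mean exponential shearing distance in bp; must be positive.
#' @return An object of class `"GlobalShape"`: a list with elements `sigma`
#'   and `beta`.
#' @seealso [density_right()], [fit_global()]
#' @examples
#' global_shape(40, 60)
#' @export
global_shape <- function(sigma = 30, beta = 50) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (sigma <= 0 || beta <= 0)
    stop("'sigma' and 'beta' must be strictly positive")
  structure(list(sigma = as.numeric(sigma), beta = as.numeric(beta)),
            class = "GlobalShape")
}

#' @export
print.GlobalShape <- function(x, ...) {
  cat(sprintf("GlobalShape: sigma = %.4g bp, beta = %.4g bp\n",
              x$sigma, x$beta))
  invisible(x)
}

#' Per-region model parameters
#'
#' Parameters of one candidate region: `mu`, the binding-site center
#' coordinate (bp); `nu`, the expected number of tags per strand contributed
#' by the binding event; and `rho`, the locally uniform background intensity
#' (tags per bp per strand). `nu` and `rho` are shared between strands.
#'
#' @param mu Binding-site center coordinate (finite).
#' @param nu Expected binding tags per strand; `nu >= 0`.
#' @param rho Background tag intensity per bp per strand; `rho > 0`.
#' @return An object of class `"RegionParams"`.
#' @export
region_params <- function(mu, nu, rho) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (nu < 0) stop("'nu' must be non-negative")
  if (rho <= 0) stop("'rho' must be strictly positive")
  structure(list(mu = as.numeric(mu), nu = as.numeric(nu),
                 rho = as.numeric(rho)),
            class = "RegionParams")
}

#' @export
print.RegionParams <- function(x, ...) {
  cat(sprintf("RegionParams: mu = %.2f, nu = %.2f, rho = %.4f\n",
              x$mu, x$nu, x$rho))
  invisible(x)
}

## centered exponentially-modified-Gaussian log density: t = x - mu.
## log f = log Phi(t/sigma - sigma/beta) - log beta - t/beta + sigma^2/(2 beta^2),
## kept in log space so the exp factor cannot overflow for t << 0.
emg_log_density <- function(t, sigma, beta) {
  stats::pnorm(t / sigma - sigma / beta, log.p = TRUE) -
    log(beta) - t / beta + sigma^2 / (2 * beta^2)
}

## d/dt of the centered density; used by analytic likelihood gradients.
emg_density_deriv <- function(t, sigma, beta) {
  u <- t / sigma - sigma / beta
  logh <- -log(beta) - t / beta + sigma^2 / (2 * beta^2)
  exp(stats::dnorm(u, log = TRUE) - log(sigma) + logh) -
    exp(stats::pnorm(u, log.p = TRUE) + logh) / beta
}

check_coords <- function(x, mu) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("coordinates must be finite numbers")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("'mu' must be a single finite number")
}

#' Tag-location densities around one binding event
#'
#' `density_right()` is the marginal density of a reverse-strand ("right")
#' tag location: the convolution of a normal cross-link position
#' `N(mu, sigma^2)` with an exponential shearing distance of mean `beta`,
#' i.e. an exponentially modified Gaussian skewed downstream of `mu`.
#' `density_left()` is its mirror image around `mu` and describes
#' forward-strand ("left") tags: `f_L(mu - z) = f_R(mu + z)`.
#'
#' @param x Coordinate(s) at which to evaluate the density (bp); vectorized.
#' @param mu Binding-site center coordinate.
#' @param shape A [global_shape()] object.
#' @return Density value(s) per bp; non-negative and finite for all finite
#'   `x`.
#' @examples
#' sh <- global_shape(40, 60)
#' density_right(0:10, mu = 0, shape = sh)
#' @export
density_right <- function(x, mu, shape) {
  stopifnot(inherits(shape, "GlobalShape"))
  check_coords(x, mu)
  exp(emg_log_density(x - mu, shape$sigma, shape$beta))
}

#' @rdname density_right
#' @export
density_left <- function(x, mu, shape) {
  stopifnot(inherits(shape, "GlobalShape"))
  check_coords(x, mu)
  exp(emg_log_density(mu - x, shape$sigma, shape$beta))
}

## distribution function of the centered right-tag density; closed form of
## the ex-Gaussian CDF, used by simulation calibration checks.
emg_cdf <- function(t, sigma, beta) {
  stats::pnorm(t / sigma) -
    exp(stats::pnorm(t / sigma - sigma / beta, log.p = TRUE) -
          t / beta + sigma^2 / (2 * beta^2))
}

#' Expected tag count at a position
#'
#' The Poisson intensity of the model at position `j`:
#' `lambda_j = nu * f_strand(j | mu, sigma, beta) + rho`, where `f_strand`
#' is [density_right()] or [density_left()].
#'
#' @param j Position(s), bp; vectorized.
#' @param strand `"left"` (forward-strand tags) or `"right"`
#'   (reverse-strand tags).
#' @param params A [region_params()] object.
#' @param shape A [global_shape()] object.
#' @return Expected tag count(s) at `j`; strictly positive.
#' @export
intensity <- function(j, strand = c("left", "right"), params, shape) {
  strand <- match.arg(strand)
  stopifnot(inherits(params, "RegionParams"))
  f <- if (strand == "right") density_right(j, params$mu, shape)
       else density_left(j, params$mu, shape)
  params$nu * f + params$rho
}

#' Per-position tag counts of one candidate region
#'
#' Container for the data of one region: strand-specific tag counts at each
#' position together with the mask of unmappable positions (positions whose
#' tag sequence is not unique in the genome). Counts at unmappable positions
#' must be zero -- those positions are censored and contribute nothing to
#' the likelihood.
#'
#' @param counts_left,counts_right Non-negative integer vectors of equal
#'   length `width`: forward-strand and reverse-strand tag counts per
#'   position.
#' @param start First genomic coordinate of the region (1-based, inclusive).
#' @param unmappable_left,unmappable_right Logical vectors of length `width`
#'   (default: all mappable).
#' @return An object of class `"RegionTags"` with fields `start`, `width`,
#'   `counts_left`, `counts_right`, `unmappable_left`, `unmappable_right`.
#' @export
region_tags <- function(counts_left, counts_right, start = 1L,
                        unmappable_left = NULL, unmappable_right = NULL) {
  w <- length(counts_left)
  if (w < 1L) stop("region width must be >= 1")
  if (length(counts_right) != w)
    stop("'counts_left' and 'counts_right' must have the same length")
  if (is.null(unmappable_left)) unmappable_left <- logical(w)
  if (is.null(unmappable_right)) unmappable_right <- logical(w)
  stopifnot(is.logical(unmappable_left), length(unmappable_left) == w,
            is.logical(unmappable_right), length(unmappable_right) == w,
            length(start) == 1L, is.finite(start))
  for (cnt in list(counts_left, counts_right)) {
    if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt < 0) ||
        any(cnt != round(cnt)))
      stop("counts must be non-negative integers")
  }
  if (any(counts_left[unmappable_left] > 0) ||
      any(counts_right[unmappable_right] > 0))
    stop("non-zero tag count at an unmappable position")
  structure(list(start = as.numeric(start), width = w,
                 counts_left = as.numeric(counts_left),
                 counts_right = as.numeric(counts_right),
                 unmappable_left = unmappable_left,
                 unmappable_right = unmappable_right),
            class = "RegionTags")
}

#' @export
print.RegionTags <- function(x, ...) {
  cat(sprintf(
    "RegionTags: [%d, %d] (width %d), %d left + %d right tags, %d/%d unmappable positions\n",
    as.integer(x$start), as.integer(x$start + x$width - 1), x$width,
    sum(x$counts_left), sum(x$counts_right),
    sum(x$unmappable_left) + sum(x$unmappable_right), 2L * x$width))
  invisible(x)
}

region_positions <- function(tags) tags$start + seq_len(tags$width) - 1

n_mappable <- function(tags) {
  sum(!tags$unmappable_left) + sum(!tags$unmappable_right)
}

total_tags <- function(tags) sum(tags$counts_left) + sum(tags$counts_right)

#' Region log-likelihood under the two-peak Poisson model
#'
#' Sum over all mappable positions, on both strands, of the Poisson log
#' probability of the observed count at the model intensity
#' ([intensity()]). Unmappable positions are censored: they contribute
#' nothing.
#'
#' @param tags A [region_tags()] object.
#' @param params A [region_params()] object.
#' @param shape A [global_shape()] object.
#' @return The log-likelihood (a single number; 0 when every position is
#'   unmappable).
#' @export
region_log_likelihood <- function(tags, params, shape) {
  stopifnot(inherits(tags, "RegionTags"))
  pos <- region_positions(tags)
  ll <- 0
  mL <- !tags$unmappable_left
  if (any(mL)) {
    lamL <- intensity(pos[mL], "left", params, shape)
    ll <- ll + sum(stats::dpois(tags$counts_left[mL], lamL, log = TRUE))
  }
  mR <- !tags$unmappable_right
  if (any(mR)) {
    lamR <- intensity(pos[mR], "right", params, shape)
    ll <- ll + sum(stats::dpois(tags$counts_right[mR], lamR, log = TRUE))
  }
  ll
}
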