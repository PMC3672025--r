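## Independent oracles used across the suite. Each re-derives a quantity by
## brute force or quadrature, never through the code path it checks.

## right-tag density by direct numeric convolution of the normal cross-link
## density with the exponential shearing density
quad_density_right <- function(x, mu, sigma, beta) {
  vapply(x, function(xx) {
    ## integrand support: xi within the normal spike and xi <= x
    lo <- mu - 13 * sigma
    hi <- min(xx, mu + 13 * sigma)
    if (hi <= lo) return(0)
    stats::integrate(function(xi) {
      stats::dexp(xx - xi, rate = 1 / beta) * stats::dnorm(xi, mu, sigma)
    }, lower = lo, upper = hi, rel.tol = 1e-13, abs.tol = 1e-13)$value
  }, 0)
}

## closed-form ex-Gaussian CDF of the centered right-tag offset,
## derived independently of the package's log-space density
emg_cdf_oracle <- function(t, sigma, beta) {
  stats::pnorm(t / sigma) -
    exp(-t / beta + sigma^2 / (2 * beta^2)) *
    stats::pnorm(t / sigma - sigma / beta)
}

## brute-force region selector: every window start is tested directly; runs
## of qualifying starts are padded to a full window and merged on a boolean
## array
bf_select_regions <- function(pos, window, min_count) {
  M <- max(pos)
  cnt <- tabulate(pos, nbins = M + window)
  qual <- vapply(seq_len(M), function(p) {
    sum(cnt[p:(p + window - 1)]) >= min_count
  }, TRUE)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a <- starts[r$values]
  b <- pmax(ends[r$values], a + window - 1L)
  covered <- logical(M + window)
  for (i in seq_along(a)) covered[a[i]:b[i]] <- TRUE
  rr <- rle(covered)
  e2 <- cumsum(rr$lengths)
  s2 <- e2 - rr$lengths + 1L
  data.frame(start = s2[rr$values], end = e2[rr$values])
}

## exact segment-score tail probabilities by enumerating all 4^L segments
bf_score_table <- function(scores) {
  L <- ncol(scores)
  combos <- as.matrix(expand.grid(rep(list(1:4), L)))
  totals <- vapply(seq_len(nrow(combos)), function(i) {
    sum(scores[cbind(combos[i, ], seq_len(L))])
  }, 0)
  totals
}

## random region-tag fixture (count-mode draw written out longhand so it
## does not depend on the package simulator)
random_region_fixture <- function(width, mu, nu, rho, shape) {
  pos <- seq_len(width)
  lamL <- nu * density_left(pos, mu, shape) + rho
  lamR <- nu * density_right(pos, mu, shape) + rho
  region_tags(rpois(width, lamL), rpois(width, lamR))
}
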