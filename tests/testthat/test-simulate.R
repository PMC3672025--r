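sh <- global_shape(40, 60)

test_that("background-only simulation hits the nominal rate on both strands", {
  tg <- simulate_region(1000, sh, nu = 0, rho = 0.2, seed = 701)
  se <- sqrt(0.2 / 1000)
  expect_lt(abs(mean(tg$counts_left) - 0.2), 3 * se)
  expect_lt(abs(mean(tg$counts_right) - 0.2), 3 * se)
  expect_equal(attr(tg, "truth")$nu, 0)
})

test_that("mechanistic tag offsets follow the closed-form density", {
  tg <- simulate_region(4000, sh, mu = 2000, nu = 5000, rho = 0,
                        mode = "mechanistic", seed = 702)
  off <- attr(tg, "truth")$offsets_right
  n <- length(off)
  expect_gt(n, 4500)

  ## mean offset = beta (the ex-Gaussian first moment about mu)
  se_mean <- sqrt(40^2 + 60^2) / sqrt(n)
  expect_lt(abs(mean(off) - 60), 3 * se_mean)

  ## Kolmogorov-Smirnov against the independently derived ex-Gaussian CDF
  ks <- suppressWarnings(
    ks.test(off, function(q) emg_cdf_oracle(q, 40, 60)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n))   # 1% critical value

  ## left offsets mirror the right ones in distribution
  offL <- attr(tg, "truth")$offsets_left
  ksm <- suppressWarnings(ks.test(-offL,
                                  function(q) emg_cdf_oracle(q, 40, 60)))
  expect_lt(unname(ksm$statistic), 1.63 / sqrt(length(offL)))
})

test_that("count mode and mechanistic mode agree in distribution", {
  tgc <- simulate_region(1200, sh, mu = 600, nu = 40000, rho = 5,
                         mode = "count", seed = 703)
  tgm <- simulate_region(1200, sh, mu = 600, nu = 40000, rho = 5,
                         mode = "mechanistic", seed = 704)
  bins <- rep(1:24, each = 50)
  tab <- rbind(
    c(tapply(tgc$counts_left, bins, sum), tapply(tgc$counts_right, bins, sum)),
    c(tapply(tgm$counts_left, bins, sum), tapply(tgm$counts_right, bins, sum)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("censoring zeroes exactly the masked positions", {
  ## replay the documented draw order (mask, left counts, right counts)
  ## with the same seed and compare the uncensored stream
  set.seed(705)
  width <- 600
  mask <- runif(width) < 0.3
  pos <- 1:width
  lamL <- 150 * density_left(pos, 300, sh) + 0.2
  lamR <- 150 * density_right(pos, 300, sh) + 0.2
  yl <- rpois(width, lamL); yr <- rpois(width, lamR)

  tg <- simulate_region(width, sh, mu = 300, nu = 150, rho = 0.2,
                        unmappable_frac = 0.3,
                        unmappable_mode = "bernoulli", seed = 705)
  expect_identical(tg$unmappable_left, mask)
  expect_true(all(tg$counts_left[mask] == 0))
  expect_true(all(tg$counts_right[mask] == 0))
  expect_identical(tg$counts_left[!mask], as.numeric(yl[!mask]))
  expect_identical(tg$counts_right[!mask], as.numeric(yr[!mask]))
})

test_that("a planted site outside the region warns about truncation", {
  expect_warning(simulate_region(100, sh, mu = 500, nu = 50, seed = 706),
                 "truncated")
})

test_that("dataset files conserve tags, round-trip, and obey the seeding contract", {
  peaks <- data.frame(chrom = rep(c("chrA", "chrB"), c(2, 1)),
                      mu = c(3000, 9000, 5000), nu = c(120, 200, 150))
  lens <- c(chrA = 12000, chrB = 8000)
  d1 <- file.path(tempdir(), "simds1")
  sim <- simulate_dataset(peaks, lens, sh, rho = 0.03,
                          unmappable_frac = 0.05, dir = d1,
                          prefix = "a", seed = 801)

  ## conservation: one BED line per retained tag
  expect_equal(length(readLines(sim$tags_path)), length(sim$tags))

  ## round-trip through the reader reproduces the in-memory tags exactly
  back <- read_mapped_tags(sim$tags_path, "bed")
  expect_equal(sort(paste(GenomicRanges::seqnames(back),
                          GenomicRanges::start(back),
                          GenomicRanges::strand(back))),
               sort(paste(GenomicRanges::seqnames(sim$tags),
                          GenomicRanges::start(sim$tags),
                          GenomicRanges::strand(sim$tags))))

  ## no tag sits at a censored position
  expect_equal(sum(GenomicRanges::countOverlaps(back, sim$unmappable)), 0)

  ## truth table lists every planted event
  truth <- read.table(sim$truth_path, header = TRUE, sep = "\t")
  expect_equal(truth$mu, peaks$mu)

  ## same seed -> identical files; different seed -> different draw
  sim2 <- simulate_dataset(peaks, lens, sh, rho = 0.03,
                           unmappable_frac = 0.05,
                           dir = file.path(tempdir(), "simds2"),
                           prefix = "a", seed = 801)
  expect_identical(readLines(sim$tags_path), readLines(sim2$tags_path))
  sim3 <- simulate_dataset(peaks, lens, sh, rho = 0.03,
                           unmappable_frac = 0.05,
                           dir = file.path(tempdir(), "simds3"),
                           prefix = "a", seed = 802)
  expect_false(identical(readLines(sim$tags_path),
                         readLines(sim3$tags_path)))
})
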