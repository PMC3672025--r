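## Synthetic ChIP-seq tag data with exactly the statistical structure the
## model assumes: normal cross-links, exponential shearing, strand
## projection, uniform background, optional censoring of unmappable
## positions.

round_half_up <- function(x) floor(x + 0.5)

## unmappable mask over 'width' positions: i.i.d. Bernoulli or planted
## contiguous blocks (of 20-80 bp) totalling about 'frac' of the region
unmappable_mask <- function(width, frac, mode = c("block", "bernoulli")) {
  mode <- match.arg(mode)
  mask <- logical(width)
  if (frac <= 0) return(mask)
  if (frac >= 1) return(!mask)
  if (mode == "bernoulli") return(stats::runif(width) < frac)
  target <- round(frac * width)
  guard <- 0L
  while (sum(mask) < target && guard < 10000L) {
    guard <- guard + 1L
    len <- min(sample(20:80, 1L), target - sum(mask) + 19L)
    at <- sample.int(max(width - len + 1L, 1L), 1L)
    mask[at:min(at + len - 1L, width)] <- TRUE
  }
  mask
}

#' Simulate one region of tag counts
#'
#' Generates strand-specific per-position tag counts for a region under the
#' two-peak model, in either of two equivalent modes:
#' \describe{
#'   \item{`count`}{draw `Y_j` independently Poisson at the model intensity
#'     `nu * f_strand(j) + rho` on each strand.}
#'   \item{`mechanistic`}{replay the generative story: a Poisson(`nu`)
#'     number of tags per strand, each at `round(xi + E)` (right) or
#'     `round(xi - E)` (left) with `xi ~ N(mu, sigma^2)`,
#'     `E ~ Exp(mean beta)`, plus uniform background tags at rate `rho` per
#'     position per strand.}
#' }
#' Counts at unmappable positions are then zeroed (censoring), mirroring
#' what mapping ambiguity does to real data.
#'
#' @param width Region width in bp.
#' @param shape A [global_shape()] object.
#' @param mu Binding-site center, genomic coordinate (default: region
#'   midpoint). A `mu` outside the region triggers a warning (truncated
#'   signal).
#' @param nu Expected binding tags per strand (0 = background only).
#' @param rho Background intensity, tags per bp per strand.
#' @param start First coordinate of the region (1-based).
#' @param mode `"count"` or `"mechanistic"`.
#' @param unmappable_frac Fraction of positions to censor.
#' @param unmappable_mode `"block"` (contiguous planted blocks) or
#'   `"bernoulli"` (i.i.d.).
#' @param seed Optional integer seed applied via [set.seed()] before
#'   drawing.
#' @return A [region_tags()] object with an attribute `"truth"`: a list
#'   holding the generating parameters, the mode, and (mechanistic mode)
#'   the unrounded signal-tag offsets from `mu` on each strand.
#' @export
simulate_region <- function(width, shape, mu = NULL, nu = 0, rho = 0.1,
                            start = 1L, mode = c("count", "mechanistic"),
                            unmappable_frac = 0,
                            unmappable_mode = c("block", "bernoulli"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(shape, "GlobalShape"), width >= 1, nu >= 0, rho >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mu)) mu <- start + (width - 1) / 2
  end <- start + width - 1
  if (nu > 0 && (mu < start || mu > end))
    warning("'mu' lies outside the region; the planted signal is truncated")
  pos <- start:end
  um <- unmappable_mask(width, unmappable_frac, unmappable_mode)
  truth <- list(mu = mu, nu = nu, rho = rho, sigma = shape$sigma,
                beta = shape$beta, mode = mode, unmappable = um)

  if (mode == "count") {
    lamL <- nu * density_left(pos, mu, shape) + rho
    lamR <- nu * density_right(pos, mu, shape) + rho
    cl <- stats::rpois(width, lamL)
    cr <- stats::rpois(width, lamR)
  } else {
    nR <- stats::rpois(1, nu)
    offR <- stats::rnorm(nR, 0, shape$sigma) + stats::rexp(nR, 1 / shape$beta)
    nL <- stats::rpois(1, nu)
    offL <- -(stats::rnorm(nL, 0, shape$sigma) + stats::rexp(nL, 1 / shape$beta))
    bgL <- if (rho > 0) sample.int(width, stats::rpois(1, rho * width),
                                   replace = TRUE) else integer()
    bgR <- if (rho > 0) sample.int(width, stats::rpois(1, rho * width),
                                   replace = TRUE) else integer()
    posL <- c(round_half_up(mu + offL), start + bgL - 1L)
    posR <- c(round_half_up(mu + offR), start + bgR - 1L)
    cl <- tabulate(posL[posL >= start & posL <= end] - start + 1, width)
    cr <- tabulate(posR[posR >= start & posR <= end] - start + 1, width)
    truth$offsets_left <- offL
    truth$offsets_right <- offR
  }
  cl[um] <- 0L                        # censoring
  cr[um] <- 0L
  out <- region_tags(cl, cr, start = start,
                     unmappable_left = um, unmappable_right = um)
  attr(out, "truth") <- truth
  out
}

#' Simulate a multi-peak, multi-chromosome tag dataset on disk
#'
#' Plants one binding event per row of `peaks` (mechanistic mode), adds
#' uniform background along every chromosome, optionally censors planted
#' unmappable blocks, and writes the three files the pipeline consumes: a
#' 6-column BED of tag locations, a BED of unmappable intervals, and a TSV
#' truth table of the planted events.
#'
#' @param peaks Data frame with columns `chrom`, `mu`, `nu`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param shape A [global_shape()] object.
#' @param rho Background intensity, tags per bp per strand.
#' @param unmappable_frac Fraction of each chromosome to censor (planted
#'   blocks).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param seed Integer seed (required: the generator is part of the test
#'   surface and must be reproducible).
#' @return Invisibly, a list with `tags_path`, `mappability_path`,
#'   `truth_path`, the tag `GRanges`, the unmappable `GRanges`, and the
#'   truth data frame.
#' @export
simulate_dataset <- function(peaks, chrom_lengths, shape, rho = 0.05,
                             unmappable_frac = 0, dir = tempdir(),
                             prefix = "simulated", seed) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "mu", "nu") %in% names(peaks)),
            all(peaks$chrom %in% names(chrom_lengths)),
            !missing(seed))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  chrom <- character(); pos <- integer(); std <- character()
  um_list <- list()
  for (ch in names(chrom_lengths)) {
    len <- as.integer(chrom_lengths[[ch]])
    um <- unmappable_mask(len, unmappable_frac, "block")
    for (i in which(peaks$chrom == ch)) {
      nR <- stats::rpois(1, peaks$nu[i])
      pR <- round_half_up(peaks$mu[i] +
                            stats::rnorm(nR, 0, shape$sigma) +
                            stats::rexp(nR, 1 / shape$beta))
      nL <- stats::rpois(1, peaks$nu[i])
      pL <- round_half_up(peaks$mu[i] -
                            stats::rnorm(nL, 0, shape$sigma) -
                            stats::rexp(nL, 1 / shape$beta))
      pos <- c(pos, pL, pR)
      std <- c(std, rep("+", nL), rep("-", nR))
      chrom <- c(chrom, rep(ch, nL + nR))
    }
    nbg <- stats::rpois(2, rho * len)
    pos <- c(pos, sample.int(len, nbg[1], replace = TRUE),
             sample.int(len, nbg[2], replace = TRUE))
    std <- c(std, rep("+", nbg[1]), rep("-", nbg[2]))
    chrom <- c(chrom, rep(ch, sum(nbg)))
    if (any(um)) {
      r <- IRanges::reduce(IRanges::IRanges(which(um), width = 1))
      um_list[[ch]] <- data.frame(chrom = ch, start = IRanges::start(r),
                                  end = IRanges::end(r))
    }
  }
  keep <- pos >= 1
  for (ch in names(chrom_lengths))
    keep <- keep & !(chrom == ch & pos > chrom_lengths[[ch]])
  chrom <- chrom[keep]; pos <- pos[keep]; std <- std[keep]
  unmappable <- if (length(um_list)) {
    df <- do.call(rbind, um_list)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  } else GenomicRanges::GRanges()
  if (length(unmappable)) {        # censor tags at unmappable positions
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    hit <- GenomicRanges::countOverlaps(gr, unmappable) > 0
    chrom <- chrom[!hit]; pos <- pos[!hit]; std <- std[!hit]
  }
  ord <- order(chrom, pos, std)
  chrom <- chrom[ord]; pos <- pos[ord]; std <- std[ord]

  tags_path <- file.path(dir, paste0(prefix, "_tags.bed"))
  utils::write.table(
    data.frame(chrom, pos - 1L, pos, paste0("tag", seq_along(pos)), 0L, std),
    tags_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  mappability_path <- file.path(dir, paste0(prefix, "_unmappable.bed"))
  utils::write.table(
    if (length(unmappable)) {
      data.frame(as.character(GenomicRanges::seqnames(unmappable)),
                 GenomicRanges::start(unmappable) - 1L,
                 GenomicRanges::end(unmappable))
    } else data.frame(character(), integer(), integer()),
    mappability_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  truth <- peaks[c("chrom", "mu", "nu")]
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(tags_path = tags_path, mappability_path = mappability_path,
                 truth_path = truth_path,
                 tags = GenomicRanges::GRanges(
                   chrom, IRanges::IRanges(pos, width = 1), strand = std),
                 unmappable = unmappable, truth = truth))
}
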