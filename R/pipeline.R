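## The five-step peak-calling pipeline: read tags, select regions, train or
## accept (sigma, beta), fit and test every region, rank, screen, recommend
## cut-offs; plus the motif-based evaluation metrics and output writers.

#' Call peaks from mapped tags
#'
#' Runs the whole pipeline: (1) read the mapped-tag file (or accept a tag
#' `GRanges`); (2) select candidate regions by windowed counts
#' ([select_regions()]); (3) take the supplied global shape, train one from
#' motif anchors ([fit_global()]) when `motif_sites` is given, or fall back
#' to the defaults `sigma = 30`, `beta = 50`; (4) fit every region
#' ([fit_region()]), with binding and goodness-of-fit tests and standard
#' errors; (5) rank by estimated binding intensity `2*nu` and, when
#' screening cutoffs are supplied, flag screened peaks. Deterministic given
#' its inputs.
#'
#' @param tags Path to a tag file, or a tag `GRanges`.
#' @param format Tag-file dialect for [read_mapped_tags()].
#' @param mappability Optional path to a BED of unmappable intervals, or a
#'   `GRanges`.
#' @param shape Optional [global_shape()]; overrides training.
#' @param motif_sites Optional data frame (`chrom`, `position`) of motif
#'   sites used to train `(sigma, beta)` when `shape` is absent.
#' @param window,min_count Region-selection parameters (defaults 150, 15).
#' @param screen_length,screen_pvalue Optional screening cutoffs, applied
#'   via [screen_peaks()].
#' @return A `data.frame` of peak calls (one row per selected region),
#'   ordered by rank, with the fitted shape in attribute `"shape"`.
#'   Columns include `chrom`, `start`, `end`, `width`, `site` (the
#'   estimated binding location), `se_mu`, `nu`, `binding_intensity`
#'   (`2*nu`), `rho`, `lr_stat`, `lr_pvalue`, `gof_stat`, `gof_df`,
#'   `gof_pvalue`, `converged`, `screened`, `rank`.
#' @export
call_peaks <- function(tags, format = c("bed", "sam", "bowtie"),
                       mappability = NULL, shape = NULL,
                       motif_sites = NULL, window = 150L, min_count = 15L,
                       screen_length = NULL, screen_pvalue = NULL) {
  if (is.character(tags)) tags <- read_mapped_tags(tags, match.arg(format))
  if (is.character(mappability)) mappability <- read_mappability(mappability)
  regions <- select_regions(tags, window = window, min_count = min_count)
  if (length(regions) == 0L) {
    warning("no candidate regions reach the minimum window count")
    out <- empty_peaks()
    attr(out, "shape") <- if (is.null(shape)) global_shape() else shape
    return(out)
  }
  region_data <- lapply(seq_along(regions), function(i)
    region_tags_from_granges(tags, regions[i], mappability))

  if (is.null(shape)) {
    shape <- if (!is.null(motif_sites) && nrow(motif_sites) > 0) {
      anchored <- anchor_regions(regions, region_data, motif_sites)
      fit_global(anchored$training, anchored$anchors)
    } else global_shape()            # documented defaults sigma=30, beta=50
  }

  rows <- lapply(seq_along(regions), function(i) {
    fit <- fit_region(region_data[[i]], shape)
    p <- fit$params_hat
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions[i])),
      start = GenomicRanges::start(regions[i]),
      end = GenomicRanges::end(regions[i]),
      width = GenomicRanges::width(regions[i]),
      total_count = fit$n_tags,
      site = p$mu, se_mu = fit$se_mu,
      nu = p$nu, se_nu = fit$se_nu,
      binding_intensity = 2 * p$nu,
      rho = p$rho,
      loglik = fit$loglik, null_loglik = fit$null_loglik,
      lr_stat = fit$lr_stat, lr_pvalue = fit$lr_pvalue,
      gof_stat = fit$gof_stat, gof_df = fit$gof_df,
      gof_pvalue = fit$gof_pvalue,
      converged = fit$converged,
      stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  peaks$screened <- FALSE
  peaks <- if (!is.null(screen_length) && !is.null(screen_pvalue)) {
    screen_peaks(peaks, screen_length, screen_pvalue)
  } else rank_peaks(peaks)
  attr(peaks, "shape") <- shape
  peaks
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             width = integer(), total_count = integer(), site = numeric(),
             se_mu = numeric(), nu = numeric(), se_nu = numeric(),
             binding_intensity = numeric(), rho = numeric(),
             loglik = numeric(), null_loglik = numeric(),
             lr_stat = numeric(), lr_pvalue = numeric(),
             gof_stat = numeric(), gof_df = integer(),
             gof_pvalue = numeric(), converged = logical(),
             screened = logical(), rank = integer())
}

## pair training regions with the motif site nearest their midpoint
anchor_regions <- function(regions, region_data, motif_sites) {
  training <- list(); anchors <- numeric()
  for (i in seq_along(regions)) {
    ch <- as.character(GenomicRanges::seqnames(regions[i]))
    cand <- motif_sites[motif_sites$chrom == ch, , drop = FALSE]
    if (nrow(cand) == 0L) next
    inside <- cand$position >= GenomicRanges::start(regions[i]) &
      cand$position <= GenomicRanges::end(regions[i])
    if (!any(inside)) next
    mid <- (GenomicRanges::start(regions[i]) +
              GenomicRanges::end(regions[i])) / 2
    site <- cand$position[inside][which.min(abs(cand$position[inside] - mid))]
    training <- c(training, list(region_data[[i]]))
    anchors <- c(anchors, site)
  }
  list(training = training, anchors = anchors)
}

#' Rank peaks by estimated binding intensity
#'
#' Unscreened, converged peaks are ranked 1..N by descending
#' `binding_intensity` (`2*nu`), ties broken by smaller binding p-value,
#' then by chromosome and coordinate; the ranking is therefore invariant to
#' the input row order. Non-converged fits follow with `rank = NA`;
#' screened peaks come last, retained with their flag.
#'
#' @param peaks A peak-call data frame (see [call_peaks()]).
#' @return The data frame reordered, with the `rank` column rebuilt.
#' @export
rank_peaks <- function(peaks) {
  if (!"screened" %in% names(peaks)) peaks$screened <- FALSE
  peaks$rank <- NA_integer_
  eligible <- which(!peaks$screened & peaks$converged)
  ord <- eligible[order(-peaks$binding_intensity[eligible],
                        peaks$lr_pvalue[eligible],
                        peaks$chrom[eligible],
                        peaks$start[eligible])]
  peaks$rank[ord] <- seq_along(ord)
  rest <- setdiff(seq_len(nrow(peaks)), ord)
  rest <- rest[order(peaks$screened[rest], peaks$chrom[rest],
                     peaks$start[rest])]
  out <- peaks[c(ord, rest), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen peaks by region length and goodness-of-fit p-value
#'
#' A peak is screened (masked from the ranking, but retained in the output
#' with its flag) iff its region is shorter than `max_length` *and* its
#' goodness-of-fit p-value is below `min_gof_pvalue`: short ill-fitting
#' regions are characteristic of PCR spikes, while long ill-fitting regions
#' are kept as candidate multiple-binding regions. Peaks with an undefined
#' goodness-of-fit test are kept. Fit values are never altered; only flags
#' and ranks change.
#'
#' @param peaks A peak-call data frame.
#' @param max_length Region-length cutoff in bp.
#' @param min_gof_pvalue Goodness-of-fit p-value cutoff.
#' @return The data frame with `screened` flags set and ranks rebuilt.
#' @export
screen_peaks <- function(peaks, max_length, min_gof_pvalue) {
  stopifnot(is.numeric(max_length), is.numeric(min_gof_pvalue))
  peaks$screened <- peaks$width < max_length &
    !is.na(peaks$gof_pvalue) & peaks$gof_pvalue < min_gof_pvalue
  rank_peaks(peaks)
}

#' Recommend screening cutoffs from motif sites
#'
#' Grid search over length cutoffs `{200, 300, 400, 500}` and p-value
#' cutoffs `{1e-2, 1e-4, 1e-6, 1e-8}`: for each pair the peaks are
#' screened, evaluated against the motif sites, and scored by the area
#' under the precision-vs-rank curve truncated at rank `min(10000, N)`.
#' The maximizing pair is returned; ties go to the least aggressive pair
#' (fewest screened peaks: smallest length cutoff, then smallest p-value
#' cutoff).
#'
#' @param peaks A peak-call data frame.
#' @param motif_sites Data frame with `chrom` and `position` columns.
#' @param radius True-positive radius in bp (default 250).
#' @param lengths,pvalues The cutoff grids.
#' @param max_rank Truncation rank for the precision area (default 10000).
#' @return A list with `length_cutoff`, `pvalue_cutoff`, `auc`, and the
#'   full `grid` of candidate pairs with their areas.
#' @export
recommend_cutoffs <- function(peaks, motif_sites, radius = 250,
                              lengths = c(200, 300, 400, 500),
                              pvalues = c(1e-2, 1e-4, 1e-6, 1e-8),
                              max_rank = 10000L) {
  if (is.null(motif_sites) || nrow(motif_sites) == 0L)
    stop("motif sites are required to recommend screening cutoffs")
  grid <- expand.grid(length_cutoff = sort(lengths),
                      pvalue_cutoff = sort(pvalues))
  grid <- grid[order(grid$length_cutoff, grid$pvalue_cutoff), ]
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- screen_peaks(peaks, grid$length_cutoff[i], grid$pvalue_cutoff[i])
    ev <- evaluate_against_motifs(sp, motif_sites, radius = radius)
    pc <- ev$precision_curve
    if (length(pc) == 0L) return(0)
    sum(pc[seq_len(min(max_rank, length(pc)))])
  }, 0)
  best <- which.max(grid$auc)        # first maximum = least aggressive
  list(length_cutoff = grid$length_cutoff[best],
       pvalue_cutoff = grid$pvalue_cutoff[best],
       auc = grid$auc[best], grid = grid)
}

#' Evaluate peak calls against motif sites
#'
#' Matches every ranked (unscreened) peak to its nearest motif site on the
#' same chromosome. A peak within `radius` bp is a true positive (TP). The
#' summary reports the number of TPs, the mean absolute peak-to-site
#' distance over TPs, the mean signed bias over TPs (negative when the
#' peak lies upstream of the site, i.e. `peak - site`), and the precision
#' curve: at each rank `r`, the fraction of TPs among the top `r` peaks.
#'
#' @param peaks A peak-call data frame.
#' @param motif_sites Data frame with `chrom` and `position`, or a numeric
#'   vector of positions (single-chromosome shorthand).
#' @param radius TP radius in bp (default 250).
#' @return An object of class `"EvalSummary"`: `n_true_positive`,
#'   `mean_distance`, `mean_bias`, `precision_curve`, and the per-peak
#'   `offsets` (peak - nearest site).
#' @export
evaluate_against_motifs <- function(peaks, motif_sites, radius = 250) {
  if (is.numeric(motif_sites))
    motif_sites <- data.frame(chrom = unique(peaks$chrom)[1],
                              position = motif_sites)
  stopifnot(all(c("chrom", "position") %in% names(motif_sites)))
  ranked <- peaks[!is.na(peaks$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  off <- vapply(seq_len(nrow(ranked)), function(i) {
    cand <- motif_sites$position[motif_sites$chrom == ranked$chrom[i]]
    if (length(cand) == 0L) return(Inf)
    d <- ranked$site[i] - cand
    d[which.min(abs(d))]
  }, 0)
  tp <- abs(off) <= radius
  structure(list(
    n_true_positive = sum(tp),
    mean_distance = if (any(tp)) mean(abs(off[tp])) else NaN,
    mean_bias = if (any(tp)) mean(off[tp]) else NaN,
    precision_curve = if (nrow(ranked)) cumsum(tp) / seq_len(nrow(ranked))
                      else numeric(),
    offsets = off), class = "EvalSummary")
}

#' @export
print.EvalSummary <- function(x, ...) {
  cat(sprintf(
    "EvalSummary: %d TPs; mean distance %.1f bp; mean bias %+.1f bp\n",
    x$n_true_positive, x$mean_distance, x$mean_bias))
  invisible(x)
}

#' Average fragment length implied by the fitted shearing distance
#'
#' Each fragment end lies an average of `beta` bp from the cross-link, and
#' the location of a reverse-strand tag is the leftmost position of a
#' `tag_length`-bp read, so the average distance between the two fragment
#' ends is `2 * beta + tag_length - 1`.
#'
#' @param beta Fitted mean exponential shearing distance (bp); vectorized.
#' @param tag_length Sequenced tag length `d` in bp.
#' @return Estimated average fragment length in bp.
#' @examples
#' estimate_fragment_length(73.5, 27)   # 173.0
#' @export
estimate_fragment_length <- function(beta, tag_length) {
  stopifnot(is.numeric(beta), all(beta > 0),
            is.numeric(tag_length), all(tag_length >= 1))
  2 * beta + tag_length - 1
}

#' Write peak calls to disk
#'
#' Writes `<prefix>.bed` -- BED6 with the estimated site as a 1-bp interval
#' (0-based half-open), name `peak_<n>`, score `2*nu` -- and
#' `<prefix>.tsv` with every fit column; [read_peaks()] round-trips the
#' TSV.
#'
#' @param peaks A peak-call data frame.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_peaks <- function(peaks, prefix) {
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  if (nrow(peaks) == 0L) {
    writeLines(character(), bed_path)
    writeLines(paste(names(empty_peaks()), collapse = "\t"), tsv_path)
    return(invisible(c(bed = bed_path, tsv = tsv_path)))
  }
  site <- round(peaks$site)
  bed <- data.frame(chrom = peaks$chrom, start = site - 1L, end = site,
                    name = paste0("peak_", seq_len(nrow(peaks))),
                    score = peaks$binding_intensity, strand = ".")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(peaks, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read peak calls written by [write_peaks()]
#'
#' @param path Path to the `.tsv` file.
#' @return The peak-call data frame.
#' @export
read_peaks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
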