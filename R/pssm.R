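## Position-specific scoring matrices, exact score-distribution p-values by
## per-column convolution under the equal-base null, and sequence scanning.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a PSSM from integer-lattice scores
#'
#' Low-level constructor: a 4 x L score matrix (rows A, C, G, T) whose
#' entries are the per-column segment scores. Scores on an integer lattice
#' make the convolution p-values ([score_distribution()]) exact.
#'
#' @param scores Numeric 4 x L matrix; rows in A, C, G, T order.
#' @return An object of class `"PSSM"` with fields `scores` and `width`.
#' @seealso [pssm_from_counts()], [read_jaspar()]
#' @export
pssm_from_scores <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 4L || ncol(scores) < 1L)
    stop("'scores' must be a 4-row matrix with at least one column")
  if (any(!is.finite(scores))) stop("all PSSM scores must be finite")
  rownames(scores) <- DNA_BASES
  structure(list(scores = scores, width = ncol(scores)), class = "PSSM")
}

#' Build a log-odds PSSM from a base-count matrix
#'
#' Converts a 4 x L count matrix (e.g. a JASPAR position frequency matrix)
#' into lattice scores: per-column probabilities
#' `(count + pseudocount) / (column total + 4 * pseudocount)` are turned
#' into log2 odds against the equal-base background (1/4), scaled by
#' `scale` and rounded to integers. The default pseudocount 0.25 and scale
#' 100 keep rounding error below a hundredth of a bit per column.
#'
#' @param counts Numeric 4 x L matrix of non-negative base counts, rows in
#'   A, C, G, T order.
#' @param pseudocount Added to every cell before normalization.
#' @param scale Lattice resolution: scores are `round(scale * log2 odds)`.
#' @return A `"PSSM"` object of integer lattice scores.
#' @export
pssm_from_counts <- function(counts, pseudocount = 0.25, scale = 100) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("'counts' must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 4 * pseudocount, "/")
  pssm_from_scores(round(scale * log2(probs / 0.25)))
}

#' @export
print.PSSM <- function(x, ...) {
  cat(sprintf("PSSM: %d columns, score range [%d, %d]\n", x$width,
              sum(apply(x$scores, 2, min)), sum(apply(x$scores, 2, max))))
  invisible(x)
}

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the common JASPAR text layouts: an optional `>` header line
#' followed by four rows of counts, either bare numbers or
#' `A [ 3 21 0 ... ]` style. Rows are taken in A, C, G, T order.
#'
#' @param path Path to the PFM text file.
#' @param ... Passed on to [pssm_from_counts()].
#' @return A `"PSSM"` object.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^>", lines) & nzchar(trimws(lines))])
  if (length(lines) != 4L)
    stop("expected 4 count rows in JASPAR matrix '", path, "'")
  rows <- lapply(lines, function(l) {
    as.numeric(regmatches(l, gregexpr("[0-9.]+", l))[[1]])
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("JASPAR matrix rows have unequal lengths")
  pssm_from_counts(do.call(rbind, rows), ...)
}

#' Reverse-complement a PSSM
#'
#' The matrix that assigns to every segment the score its reverse
#' complement receives under `pssm`: rows swapped A<->T, C<->G and columns
#' reversed.
#'
#' @param pssm A `"PSSM"` object.
#' @return A `"PSSM"` object.
#' @export
reverse_complement_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "PSSM"))
  pssm_from_scores(pssm$scores[4:1, rev(seq_len(pssm$width)), drop = FALSE])
}

#' Score one DNA segment
#'
#' Sum of the per-column scores for a segment of length equal to the PSSM
#' width.
#'
#' @param pssm A `"PSSM"` object.
#' @param segment A character string over A, C, G, T of length
#'   `pssm$width`.
#' @return The segment score (single number).
#' @export
score_segment <- function(pssm, segment) {
  stopifnot(inherits(pssm, "PSSM"))
  chars <- strsplit(toupper(as.character(segment)), "")[[1]]
  if (length(chars) != pssm$width)
    stop("segment length must equal the PSSM width")
  idx <- match(chars, DNA_BASES)
  if (any(is.na(idx))) stop("segment contains non-ACGT characters")
  sum(pssm$scores[cbind(idx, seq_len(pssm$width))])
}

#' Exact null distribution of PSSM segment scores
#'
#' Under the null model that each base appears independently with equal
#' probability 1/4, the distribution of the total segment score is the
#' L-fold convolution of the per-column score distributions. Scores are
#' rounded to multiples of `lattice_step` and the convolution is carried
#' out exactly on that integer lattice (Staden's method).
#'
#' @param pssm A `"PSSM"` object.
#' @param lattice_step Lattice resolution in score units (default 1,
#'   exact for integer score matrices).
#' @return An object of class `"ScoreDistribution"`: fields `step`,
#'   `support` (lattice indices `k`, so scores are `k * step`) and `probs`
#'   (summing to 1).
#' @export
score_distribution <- function(pssm, lattice_step = 1) {
  stopifnot(inherits(pssm, "PSSM"))
  if (!is.numeric(lattice_step) || lattice_step <= 0)
    stop("'lattice_step' must be positive")
  k <- round(pssm$scores / lattice_step)
  round_err <- sum(apply(abs(pssm$scores - k * lattice_step), 2, max))
  if (round_err > lattice_step)
    warning(sprintf(
      "lattice step %g is coarse: worst-case rounding error %g score units",
      lattice_step, round_err))
  probs <- 1
  offset <- 0                       # probs[i] = P(K = offset + i - 1)
  for (col in seq_len(ncol(k))) {
    s <- k[, col]
    lo <- min(s); hi <- max(s)
    new <- numeric(length(probs) + (hi - lo))
    for (b in 1:4) {
      sh <- s[b] - lo
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs / 4
    }
    probs <- new
    offset <- offset + lo
  }
  structure(list(step = lattice_step,
                 support = offset + seq_along(probs) - 1,
                 probs = probs),
            class = "ScoreDistribution")
}

#' @export
print.ScoreDistribution <- function(x, ...) {
  cat(sprintf(
    "ScoreDistribution: lattice step %g, support [%g, %g], mass %.12f\n",
    x$step, min(x$support) * x$step, max(x$support) * x$step,
    sum(x$probs)))
  invisible(x)
}

#' Exact upper-tail p-value of a segment score
#'
#' The probability, under the equal-base null, of observing the (latticized)
#' score or higher.
#'
#' @param dist A `"ScoreDistribution"` from [score_distribution()].
#' @param score Query score(s), in the same units as the PSSM; vectorized.
#' @return P-value(s), monotone non-increasing in `score`.
#' @export
score_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "ScoreDistribution"))
  tail_from <- rev(cumsum(rev(dist$probs)))   # P(K >= support[i])
  k <- round(score / dist$step)
  i <- k - dist$support[1] + 1
  p <- numeric(length(score))
  p[i <= 1] <- 1
  p[i > length(tail_from)] <- 0
  inside <- i >= 1 & i <= length(tail_from)
  p[inside] <- tail_from[i[inside]]
  p
}

#' Scan a sequence for motif sites
#'
#' Scores every window of both strands (the reverse strand via the
#' reverse-complemented matrix) and reports windows whose exact null
#' p-value ([score_pvalue()]) is at or below the cutoff. The reported site
#' coordinate is the center of the matched window,
#' `start + floor(L/2)`. Windows containing non-ACGT characters are
#' skipped; overlapping hits are not merged.
#'
#' @param pssm A `"PSSM"` object.
#' @param sequence A character string, `DNAString`, or single-sequence
#'   `DNAStringSet`.
#' @param pvalue_cutoff Report sites with `p <= pvalue_cutoff`
#'   (default 5e-6).
#' @param lattice_step Passed to [score_distribution()].
#' @return A data frame with columns `position` (site center, 1-based on
#'   the forward coordinates), `strand`, `score`, `pvalue`, sorted by
#'   position.
#' @export
scan_sequence <- function(pssm, sequence, pvalue_cutoff = 5e-6,
                          lattice_step = 1) {
  stopifnot(inherits(pssm, "PSSM"))
  if (methods::is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- sequence[[1]]
  }
  seqchar <- toupper(as.character(sequence))
  L <- pssm$width
  n <- nchar(seqchar)
  out0 <- data.frame(position = integer(), strand = character(),
                     score = numeric(), pvalue = numeric())
  if (n < L) return(out0)
  dist <- score_distribution(pssm, lattice_step)
  codes <- match(strsplit(seqchar, "")[[1]], DNA_BASES)

  window_scores <- function(mat) {
    s <- numeric(n - L + 1)
    for (l in seq_len(L))
      s <- s + mat[cbind(codes[seq_len(n - L + 1) + l - 1], l)]
    s                                # NA where the window contains non-ACGT
  }
  hits <- function(mat, strand) {
    sc <- window_scores(mat)
    ok <- !is.na(sc)
    pv <- rep(NA_real_, length(sc))
    pv[ok] <- score_pvalue(dist, sc[ok])
    keep <- which(ok & pv <= pvalue_cutoff)
    if (!length(keep)) return(out0)
    data.frame(position = keep + L %/% 2L, strand = strand,
               score = sc[keep], pvalue = pv[keep])
  }
  res <- rbind(hits(pssm$scores, "+"),
               hits(reverse_complement_pssm(pssm)$scores, "-"))
  res[order(res$position, res$strand), , drop = FALSE]
}
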