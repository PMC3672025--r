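## Readers for mapped-tag files and mappability tracks, and windowed
## candidate-region selection.

#' Read mapped tag locations
#'
#' Reads a mapped-tag file into a `GRanges` of width-1 ranges, one per tag,
#' anchored at the tag's location (its leftmost genomic coordinate on either
#' strand, 1-based). Forward-strand (`+`) tags are the model's "left" tags;
#' reverse-strand (`-`) tags are its "right" tags.
#'
#' Supported dialects:
#' \describe{
#'   \item{`bed`}{6-column BED; location = `chromStart + 1`, strand from
#'     column 6.}
#'   \item{`sam`}{SAM text (read via Rsamtools); unmapped records are
#'     skipped, the location is the leftmost aligned coordinate, strand from
#'     the reverse flag.}
#'   \item{`bowtie`}{Bowtie default text output: columns read name, strand,
#'     reference, 0-based leftmost offset, ...}
#' }
#' Gzip-compressed input is accepted transparently for all dialects.
#'
#' @param path Path to the tag file.
#' @param format One of `"bed"`, `"sam"`, `"bowtie"`.
#' @return A `GRanges`, one range per mapped tag, with strand `+` or `-`.
#' @export
read_mapped_tags <- function(path, format = c("bed", "sam", "bowtie")) {
  format <- match.arg(format)
  switch(format,
         bed = read_tags_bed(path),
         sam = read_tags_sam(path),
         bowtie = read_tags_bowtie(path))
}

empty_tags <- function() {
  GenomicRanges::GRanges(character(), IRanges::IRanges(integer(), width = 0),
                         strand = character())
}

file_is_empty <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  length(readLines(con, n = 1L)) == 0L
}

read_tags_bed <- function(path) {
  if (file_is_empty(path)) return(empty_tags())
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*"))
    stop("BED tag file must carry a strand in column 6 for every record")
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(GenomicRanges::start(gr),
                                          width = 1),
                         strand = st)
}

read_tags_sam <- function(path) {
  if (file_is_empty(path)) return(empty_tags())
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "flag")))[[1]]
  keep <- !is.na(res$pos) & bitwAnd(res$flag, 4L) == 0L
  if (!any(keep)) return(empty_tags())
  GenomicRanges::GRanges(as.character(res$rname[keep]),
                         IRanges::IRanges(res$pos[keep], width = 1),
                         strand = as.character(res$strand[keep]))
}

read_tags_bowtie <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(empty_tags())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad))
    stop(sprintf("malformed bowtie record at line %d of '%s'",
                 bad[1], path))
  strand <- vapply(parts, `[[`, "", 2L)
  if (any(!strand %in% c("+", "-")))
    stop(sprintf("malformed strand at line %d of '%s'",
                 which(!strand %in% c("+", "-"))[1], path))
  chrom <- vapply(parts, `[[`, "", 3L)
  off <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
  if (any(is.na(off)))
    stop(sprintf("malformed offset at line %d of '%s'",
                 which(is.na(off))[1], path))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(off + 1L, width = 1),
                         strand = strand)
}

#' Read a mappability track of unmappable positions
#'
#' Reads BED intervals of *unmappable* genomic positions (positions whose
#' tag sequence is not unique in the genome) and normalizes them into a
#' reduced, non-overlapping `GRanges`; overlapping input intervals are
#' merged silently. When the file lists *mappable* intervals instead, set
#' `invert = TRUE` and supply chromosome lengths so the complement can be
#' taken.
#'
#' @param path Path to a BED file of intervals.
#' @param invert If `TRUE`, the file lists mappable intervals and the
#'   complement is returned.
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (required when `invert = TRUE`).
#' @return A reduced `GRanges` of unmappable positions.
#' @export
read_mappability <- function(path, invert = FALSE, chrom_lengths = NULL) {
  if (file_is_empty(path)) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(GenomicRanges::start(gr) < 1))
      stop("mappability intervals must have non-negative coordinates")
    gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  }
  if (invert) {
    if (is.null(chrom_lengths))
      stop("'chrom_lengths' is required when invert = TRUE")
    genome <- GenomicRanges::GRanges(
      names(chrom_lengths),
      IRanges::IRanges(1L, as.integer(chrom_lengths)))
    gr <- GenomicRanges::setdiff(genome, gr, ignore.strand = TRUE)
  }
  gr
}

#' Query unmappable membership
#'
#' @param track A `GRanges` of unmappable intervals (see
#'   [read_mappability()]).
#' @param chrom Chromosome name (single string).
#' @param positions 1-based positions to query.
#' @return Logical vector: `TRUE` where the position is unmappable.
#' @export
is_unmappable <- function(track, chrom, positions) {
  if (is.null(track) || length(track) == 0L)
    return(logical(length(positions)))
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(positions, width = 1))
  GenomicRanges::countOverlaps(q, track, ignore.strand = TRUE) > 0
}

#' Select candidate regions by windowed tag counts
#'
#' Slides a window of `window` bp across each chromosome in 1-bp steps,
#' pooling tags from both strands. Every maximal run `[a, b]` of window
#' start positions whose window count reaches `min_count` becomes the
#' region `[a, max(b, a + window - 1)]` -- the run itself, padded when
#' necessary so no region is shorter than one full window; regions that
#' overlap after padding are merged. The result is sorted and
#' non-overlapping, each region at least `window` bp long (a single
#' isolated pileup yields exactly the minimum length).
#'
#' @param tags A `GRanges` of tag locations ([read_mapped_tags()]).
#' @param window Window length in bp (default 150).
#' @param min_count Minimum tag count per window (default 15).
#' @return A sorted `GRanges` of candidate regions with a `total_count`
#'   metadata column (tags falling inside each region).
#' @export
select_regions <- function(tags, window = 150L, min_count = 15L) {
  if (window < 1L || min_count < 1L)
    stop("'window' and 'min_count' must be >= 1")
  stopifnot(methods::is(tags, "GRanges"))
  if (length(tags) == 0L) return(GenomicRanges::GRanges())
  chroms <- unique(as.character(GenomicRanges::seqnames(tags)))
  pieces <- lapply(chroms, function(ch) {
    pos <- GenomicRanges::start(tags)[
      as.character(GenomicRanges::seqnames(tags)) == ch]
    M <- max(pos)
    cov <- S4Vectors::Rle(tabulate(pos, nbins = M))
    padded <- c(cov, S4Vectors::Rle(0L, window - 1L))
    ws <- S4Vectors::runsum(padded, k = window, endrule = "drop")
    hits <- IRanges::slice(ws, lower = min_count, rangesOnly = TRUE)
    if (length(hits) == 0L) return(NULL)
    a <- IRanges::start(hits)
    b <- pmax(IRanges::end(hits), a + window - 1L)
    rg <- IRanges::reduce(IRanges::IRanges(a, b))
    data.frame(chrom = ch, start = IRanges::start(rg),
               end = IRanges::end(rg))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) return(GenomicRanges::GRanges())
  df <- do.call(rbind, pieces)
  regions <- sort(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)))
  S4Vectors::mcols(regions)$total_count <-
    GenomicRanges::countOverlaps(regions, tags, ignore.strand = TRUE)
  regions
}

#' Extract per-position region counts from tags
#'
#' Builds the [region_tags()] count vectors for one candidate region from a
#' tag `GRanges`, applying a mappability mask. Tags located at unmappable
#' positions are inconsistent input: they are dropped with a warning.
#'
#' @param tags A `GRanges` of tag locations.
#' @param region A single-range `GRanges` (or an object with `chrom`,
#'   `start`, `end`).
#' @param mappability Optional `GRanges` of unmappable intervals.
#' @return A [region_tags()] object.
#' @export
region_tags_from_granges <- function(tags, region, mappability = NULL) {
  stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
  ch <- as.character(GenomicRanges::seqnames(region))
  from <- GenomicRanges::start(region)
  to <- GenomicRanges::end(region)
  w <- to - from + 1L
  sel <- as.character(GenomicRanges::seqnames(tags)) == ch &
    GenomicRanges::start(tags) >= from & GenomicRanges::start(tags) <= to
  pos <- GenomicRanges::start(tags)[sel]
  std <- as.character(GenomicRanges::strand(tags))[sel]
  um <- is_unmappable(mappability, ch, from:to)
  bad <- um[pos - from + 1L]
  if (any(bad)) {
    warning(sprintf("%d tag(s) at unmappable positions in %s:[%d,%d] dropped",
                    sum(bad), ch, from, to))
    pos <- pos[!bad]
    std <- std[!bad]
  }
  cl <- tabulate(pos[std == "+"] - from + 1L, nbins = w)
  cr <- tabulate(pos[std == "-"] - from + 1L, nbins = w)
  region_tags(cl, cr, start = from,
              unmappable_left = um, unmappable_right = um)
}
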