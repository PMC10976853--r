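#' Genomic interval tables
#'
#' Throughout the package, genomic intervals travel as plain data frames with
#' columns `chrom`, `start`, `end` in the BED convention: 0-based, half-open
#' `[start, end)`. Conversion to and from `GenomicRanges::GRanges` (1-based,
#' closed) happens only at the boundary of interval arithmetic and file I/O,
#' through [intervals_to_granges()] and [granges_to_intervals()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start >= end))
    stop("invalid interval: start must be < end")
  if (length(chrom) && any(!nzchar(chrom)))
    stop("invalid interval: empty chromosome name")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Convert a 0-based interval table to GRanges
#' @param df data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return A `GRanges` (1-based closed) carrying any extra columns as mcols.
#' @export
intervals_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

#' Convert GRanges back to a 0-based interval table
#' @param gr a `GRanges`.
#' @return data frame with `chrom`, `start`, `end` plus any mcols.
#' @export
granges_to_intervals <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

#' Parse a UCSC-style coordinate string
#'
#' Strings such as `"Chr4:15550619-15551270"` follow the genome-browser
#' convention: 1-based, fully inclusive. They are converted to the package's
#' internal 0-based half-open representation, so the example yields
#' `start = 15550618`, `end = 15551270` (width 652).
#'
#' @param x a coordinate string `"chrom:start-end"`; commas allowed.
#' @return one-row interval table (see [genomic_intervals()]).
#' @export
parse_ucsc_coords <- function(x) {
  x <- gsub("[ ,]", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse coordinate string: ", x)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (start1 > end1) stop("start greater than end in: ", x)
  genomic_intervals(m[2], start1 - 1, end1)
}

#' Reverse complement of a DNA string
#' @param seq a single character string over A/C/G/T/N (case kept upper).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Stable interval identifiers
#'
#' Atlas intervals are named `"<chrom>:<start>-<end>"` with the 0-based
#' half-open coordinates that also appear in the exported BED, so an id can be
#' matched against the file by eye.
#' @param df interval table.
#' @return character vector of ids.
#' @export
interval_ids <- function(df) {
  sprintf("%s:%d-%d", df$chrom, as.integer(df$start), as.integer(df$end))
}

# deterministic sub-seed derivation; keeps results < 2^31 for set.seed()
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }))
  as.integer((seed * 48271 + sum(parts * 7919)) %% 2147483647)
}

# sort an interval table by (chrom, start, end)
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
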