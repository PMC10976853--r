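#' Signal matrix container
#'
#' An enhancers-by-samples matrix of H3K27ac signal with a processing stage
#' tag. Rows are atlas interval ids, columns sample ids. `raw_counts` holds
#' bin-overlap-weighted coverage sums; `normalized` holds log2(CPM + 1).
#'
#' @param values numeric matrix with dimnames.
#' @param stage `"raw_counts"` or `"normalized"`.
#' @return object of class `SignalMatrix` (list with `values`, `stage`).
#' @export
signal_matrix <- function(values, stage = c("raw_counts", "normalized")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values))) stop("signal values must be finite")
  if (any(values < 0) && stage == "raw_counts")
    stop("raw counts must be nonnegative")
  structure(list(values = values, stage = stage), class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix (%s): %d intervals x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Merge per-sample peak calls into a unified atlas
#'
#' Intervals overlapping by at least 1 bp are fused; bookended (touching but
#' non-overlapping) intervals are kept separate, so adjacent regulatory
#' elements are never silently joined. Every base covered by any input peak is
#' covered by exactly one atlas interval, and no atlas base lacks input
#' support. Ids are `"<chrom>:<start>-<end>"` in BED coordinates.
#'
#' @param peaksets list of peak sets ([peak_set()] / [read_peaks_bed()]).
#' @return a `UnifiedAtlas`: sorted disjoint interval table with unique `id`
#'   column.
#' @export
merge_peaks <- function(peaksets) {
  if (!length(peaksets)) stop("need at least one peak set")
  all_iv <- do.call(rbind, lapply(peaksets, function(p)
    as.data.frame(p)[, c("chrom", "start", "end"), drop = FALSE]))
  if (nrow(all_iv) && any(all_iv$start >= all_iv$end))
    stop("malformed peak interval: start >= end")
  if (!nrow(all_iv)) {
    atlas <- genomic_intervals(character(), integer(), integer())
    atlas$id <- character()
    return(atlas)
  }
  merged <- GenomicRanges::reduce(intervals_to_granges(all_iv), min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged)
  atlas <- granges_to_intervals(merged)
  atlas <- sort_intervals(atlas)
  rownames(atlas) <- NULL
  atlas$id <- interval_ids(atlas)
  stopifnot(!anyDuplicated(atlas$id))
  atlas
}

#' Quantify coverage signal over atlas intervals
#'
#' For every atlas interval and sample, sums bin counts weighted by the
#' fraction of each bin overlapped:
#' `value = sum(count * overlap_bp / bin_bp)`. Chromosomes absent from a
#' track contribute 0 with a warning.
#'
#' @param atlas output of [merge_peaks()].
#' @param coverages named list (by sample id) of coverage tables, or a
#'   character vector of bedGraph paths named by sample id.
#' @param sheet sample sheet; every sample must have a coverage track.
#' @return a [signal_matrix()] at stage `raw_counts`.
#' @export
quantify_signal <- function(atlas, coverages, sheet) {
  validate_sample_sheet(sheet)
  if (is.character(coverages)) {
    coverages <- stats::setNames(lapply(coverages, read_bedgraph), names(coverages))
  }
  missing <- setdiff(sheet$sample_id, names(coverages))
  if (length(missing))
    stop("no coverage for sample(s): ", paste(missing, collapse = ", "))
  atlas_gr <- intervals_to_granges(atlas[, c("chrom", "start", "end")])
  vals <- vapply(sheet$sample_id, function(sid) {
    cov <- coverages[[sid]]
    bw <- unique(cov$end - cov$start)
    if (length(bw) != 1)
      stop("bin width inconsistent within coverage track for sample ", sid)
    lost <- setdiff(unique(atlas$chrom), unique(cov$chrom))
    if (length(lost))
      warning("chromosome(s) missing from track of ", sid, ": ",
              paste(lost, collapse = ", "), " (treated as zero signal)")
    cov_gr <- intervals_to_granges(cov[, c("chrom", "start", "end")])
    hits <- GenomicRanges::findOverlaps(atlas_gr, cov_gr)
    ov <- GenomicRanges::width(IRanges::pintersect(
      atlas_gr[S4Vectors::queryHits(hits)], cov_gr[S4Vectors::subjectHits(hits)]))
    contrib <- cov$count[S4Vectors::subjectHits(hits)] * ov / bw
    out <- numeric(nrow(atlas))
    acc <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(acc))] <- acc
    out
  }, numeric(nrow(atlas)))
  vals <- matrix(vals, nrow = nrow(atlas),
                 dimnames = list(atlas$id, sheet$sample_id))
  signal_matrix(vals, "raw_counts")
}

#' Normalize a raw signal matrix
#'
#' Per column: counts-per-million scaling (`1e6 * value / column sum`)
#' followed by `log2(x + 1)` variance stabilization.
#'
#' @param m a [signal_matrix()] at stage `raw_counts`.
#' @return a [signal_matrix()] at stage `normalized`.
#' @export
normalize_signal <- function(m) {
  stopifnot(inherits(m, "SignalMatrix"))
  if (m$stage != "raw_counts") stop("normalize_signal expects stage raw_counts")
  libsize <- colSums(m$values)
  zero <- colnames(m$values)[libsize == 0]
  if (length(zero))
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  cpm <- sweep(m$values, 2, libsize, "/") * 1e6
  signal_matrix(log2(cpm + 1), "normalized")
}
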