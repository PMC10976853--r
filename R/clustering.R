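#' Pairwise sample correlation matrix
#'
#' Pearson correlation between sample columns over all atlas rows of the
#' normalized signal. The result is exactly symmetric (symmetrized, with the
#' raw asymmetry asserted below 1e-10) with a unit diagonal.
#'
#' @param m a [signal_matrix()] at stage `normalized`.
#' @return symmetric correlation matrix with sample ids as dimnames.
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "SignalMatrix"))
  if (m$stage != "normalized") stop("correlation_matrix expects normalized signal")
  v <- m$values
  if (nrow(v) < 2) stop("need at least 2 atlas rows")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance signal for sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v, method = "pearson")
  stopifnot(max(abs(r - t(r))) < 1e-10)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples
#'
#' Average-linkage (UPGMA) agglomeration on the correlation distance
#' `d = 1 - r`. Samples are ordered by label before clustering so tie-breaks
#' are deterministic.
#'
#' @param cmat a [correlation_matrix()].
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(cmat) {
  stopifnot(is.matrix(cmat), nrow(cmat) == ncol(cmat))
  ord <- order(colnames(cmat))
  d <- 1 - cmat[ord, ord]
  if (any(!is.finite(d))) stop("non-finite distance in correlation matrix")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a dendrogram as Newick
#' @param hc an `hclust` object.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Replicate cohesion score
#'
#' Fraction of eligible samples (those whose tissue has at least two samples)
#' whose highest off-diagonal correlation is with a sample of the same tissue.
#' Ties are broken by label order and flagged.
#'
#' @param cmat a [correlation_matrix()].
#' @param sheet sample sheet.
#' @return list with `score`, per-sample `report` data frame
#'   (`sample_id`, `tissue`, `nearest`, `same_tissue`, `tie`) and
#'   `excluded_tissues` (tissues with a single sample).
#' @export
replicate_cohesion <- function(cmat, sheet) {
  validate_sample_sheet(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(cmat), , drop = FALSE]
  tissue_of <- stats::setNames(sheet$tissue, sheet$sample_id)
  counts <- table(sheet$tissue)
  eligible <- sheet$sample_id[counts[sheet$tissue] >= 2]
  excluded <- names(counts)[counts < 2]
  rows <- lapply(eligible, function(sid) {
    r <- cmat[sid, setdiff(colnames(cmat), sid)]
    best <- names(r)[r == max(r)]
    best <- best[order(best)]
    data.frame(sample_id = sid, tissue = tissue_of[[sid]], nearest = best[1],
               same_tissue = tissue_of[[best[1]]] == tissue_of[[sid]],
               tie = length(best) > 1, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(score = mean(report$same_tissue), report = report,
       excluded_tissues = excluded)
}

#' Do replicates coalesce before any cross-tissue merge?
#'
#' Walks the merge sequence of an average-linkage dendrogram and tests whether
#' every tissue's samples are already united in a single cluster before the
#' first merge that joins two different tissues.
#'
#' @param hc an `hclust` over samples.
#' @param sheet sample sheet.
#' @return `TRUE`/`FALSE`.
#' @export
replicates_merge_first <- function(hc, sheet) {
  validate_sample_sheet(sheet)
  tissue_of <- stats::setNames(sheet$tissue, sheet$sample_id)
  # cluster contents after each merge step
  members <- vector("list", nrow(hc$merge))
  get_members <- function(idx) {
    if (idx < 0) hc$labels[-idx] else members[[idx]]
  }
  merged_pairs <- character()
  for (i in seq_len(nrow(hc$merge))) {
    a <- get_members(hc$merge[i, 1]); b <- get_members(hc$merge[i, 2])
    members[[i]] <- c(a, b)
    tis <- unique(tissue_of[members[[i]]])
    if (length(tis) > 1) {
      # first cross-tissue merge: every multi-sample tissue must be complete
      done <- vapply(unique(sheet$tissue), function(t) {
        ids <- sheet$sample_id[sheet$tissue == t]
        if (length(ids) < 2) return(TRUE)
        any(vapply(members[seq_len(i - 1)], function(mm)
          !is.null(mm) && all(ids %in% mm), TRUE))
      }, TRUE)
      return(all(done))
    }
  }
  TRUE
}
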