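#' Mean normalized signal per tissue group
#'
#' @param m a [signal_matrix()] at stage `normalized`.
#' @param sheet sample sheet; every column of `m` must appear in it.
#' @return matrix atlas-interval x tissue-group of arithmetic means.
#' @export
tissue_means <- function(m, sheet) {
  stopifnot(inherits(m, "SignalMatrix"))
  validate_sample_sheet(sheet)
  missing <- setdiff(colnames(m$values), sheet$sample_id)
  if (length(missing))
    stop("sample(s) absent from sheet: ", paste(missing, collapse = ", "))
  tissues <- unique(sheet$tissue)
  out <- vapply(tissues, function(t) {
    cols <- sheet$sample_id[sheet$tissue == t]
    cols <- intersect(cols, colnames(m$values))
    if (!length(cols)) stop("tissue with zero samples in matrix: ", t)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  matrix(out, nrow = nrow(m$values),
         dimnames = list(rownames(m$values), tissues))
}

#' Cross-tissue z-score matrix
#'
#' Standardizes every atlas row across tissue groups with the population
#' standard deviation: `z = (x - row mean) / row SD`. Non-constant rows come
#' out with mean 0 and population SD 1; constant rows are set to all-zero and
#' flagged in the `constant_rows` attribute.
#'
#' Note the algebraic ceiling: with `T` tissues the largest achievable entry
#' is `sqrt(T - 1)`, attained only when all other tissues are exactly equal.
#' Thresholds on z must be read against the number of tissue groups.
#'
#' @param tsig a [tissue_means()] matrix (or any rows-x-tissues matrix).
#' @return z-score matrix with logical attribute `constant_rows`.
#' @export
zscore_matrix <- function(tsig) {
  stopifnot(is.matrix(tsig))
  if (ncol(tsig) < 2) stop("need at least 2 tissue groups to z-score")
  mu <- rowMeans(tsig)
  sdp <- sqrt(rowMeans((tsig - mu)^2))
  constant <- sdp <= 1e-12
  z <- (tsig - mu) / ifelse(constant, 1, sdp)
  z[constant, ] <- 0
  attr(z, "constant_rows") <- stats::setNames(constant, rownames(tsig))
  z
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 <= 0)) stop("fewer distinct rows than clusters")
    centers[j, ] <- x[sample(n, 1, prob = d2), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' K-means assignment of enhancers to tissues
#'
#' Clusters z-score rows with Lloyd's algorithm from k-means++ seedings
#' (`restarts` independent starts, best total within-cluster sum of squares
#' kept). Each cluster is labeled by the tissue with the largest centroid
#' coordinate; clusters whose largest coordinate is below `z_label_min` are
#' labeled `"unassigned"`. Deterministic for a fixed seed.
#'
#' @param z a [zscore_matrix()].
#' @param k number of clusters; default is tissues + 1, the extra cluster
#'   absorbing broadly active enhancers.
#' @param seed integer seed.
#' @param z_label_min minimum centroid coordinate for a tissue label.
#' @param restarts number of k-means++ restarts.
#' @return data frame (`id`, `tissue`, `cluster`) with attributes `k` and
#'   `centroids`.
#' @export
kmeans_assign <- function(z, k = ncol(z) + 1, seed = 1L, z_label_min = 0.5,
                          restarts = 10) {
  stopifnot(is.matrix(z))
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(z)) stop("k exceeds the number of rows")
  run_batch <- function(s) {
    set.seed(s)
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(z, centers = kmeanspp_init(z, k),
                                       iter.max = 100, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
    best
  }
  fit <- run_batch(seed)
  if (is.null(fit)) fit <- run_batch(derive_seed(seed, "reseed"))
  if (is.null(fit))
    stop("k-means failed: empty cluster or indistinct centers after restarts")
  cent <- fit$centers
  lab <- apply(cent, 1, function(co) {
    j <- which.max(co)
    if (co[j] >= z_label_min) colnames(z)[j] else "unassigned"
  })
  out <- data.frame(id = rownames(z), tissue = unname(lab[fit$cluster]),
                    cluster = fit$cluster, stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "centroids") <- cent
  out
}

#' Tissue-unique enhancers
#'
#' The screen's uniqueness gate combines two filters: (1) the z-score of the
#' target tissue must reach `z_min`, and (2) the interval may overlap (by at
#' least 1 bp) peak calls from at most `max_ref_hits` samples of non-target
#' tissues. Either gate can be disabled. The result is ordered by descending
#' target z-score.
#'
#' @param atlas a [merge_peaks()] atlas.
#' @param z a [zscore_matrix()] over the atlas rows.
#' @param peaksets named list (by sample id) of peak sets.
#' @param sheet sample sheet.
#' @param target tissue group to screen for.
#' @param z_min z-score cutoff (default 2.0).
#' @param max_ref_hits maximum tolerated non-target samples with an
#'   overlapping peak (default 0).
#' @param use_z,use_intersection enable/disable the two gates.
#' @return character vector of atlas ids, descending target z.
#' @export
unique_enhancers <- function(atlas, z, peaksets, sheet, target,
                             z_min = 2.0, max_ref_hits = 0L,
                             use_z = TRUE, use_intersection = TRUE) {
  validate_sample_sheet(sheet)
  if (!target %in% sheet$tissue) stop("unknown target tissue: ", target)
  if (!target %in% colnames(z)) stop("target tissue absent from z matrix: ", target)
  if (is.null(names(peaksets)))
    names(peaksets) <- vapply(peaksets, attr, "", "sample_id")
  zt <- z[atlas$id, target]
  pass_z <- if (use_z) zt >= z_min else rep(TRUE, nrow(atlas))

  if (use_intersection) {
    ref_samples <- sheet$sample_id[sheet$tissue != target]
    ref_samples <- intersect(ref_samples, names(peaksets))
    atlas_gr <- intervals_to_granges(atlas[, c("chrom", "start", "end")])
    hits <- integer(nrow(atlas))
    for (sid in ref_samples) {
      p <- peaksets[[sid]]
      if (!nrow(p)) next
      ov <- IRanges::overlapsAny(
        atlas_gr, intervals_to_granges(as.data.frame(p)[, c("chrom", "start", "end")]))
      hits <- hits + as.integer(ov)
    }
    pass_int <- hits <= max_ref_hits
  } else pass_int <- rep(TRUE, nrow(atlas))

  keep <- which(pass_z & pass_int)
  atlas$id[keep][order(-zt[keep])]
}

#' Relative activity of one enhancer across tissues
#'
#' For each tissue, `(tissue mean + eps) / (grand mean over all samples +
#' eps)` of the normalized signal, with `eps = 0.5` guarding near-zero
#' denominators. A ratio of 1 means tissue activity at the cross-tissue
#' reference level.
#'
#' @param m a [signal_matrix()] at stage `normalized`.
#' @param atlas_id row id to report.
#' @param sheet sample sheet.
#' @param eps pseudo-signal (default 0.5).
#' @return data frame (`tissue`, `ratio`).
#' @export
relative_activity <- function(m, atlas_id, sheet, eps = 0.5) {
  stopifnot(inherits(m, "SignalMatrix"))
  validate_sample_sheet(sheet)
  if (!atlas_id %in% rownames(m$values)) stop("unknown atlas id: ", atlas_id)
  x <- m$values[atlas_id, ]
  grand <- mean(x)
  tissues <- unique(sheet$tissue)
  ratio <- vapply(tissues, function(t) {
    cols <- intersect(sheet$sample_id[sheet$tissue == t], names(x))
    (mean(x[cols]) + eps) / (grand + eps)
  }, 0)
  data.frame(tissue = tissues, ratio = unname(ratio), stringsAsFactors = FALSE)
}

#' Sensitivity and precision of a screened id set against planted truth
#'
#' A truth enhancer counts as recovered when any returned atlas interval
#' overlaps it by at least 1 bp; a returned interval counts as correct when it
#' overlaps any truth enhancer.
#'
#' @param atlas the unified atlas.
#' @param ids atlas ids returned by [unique_enhancers()].
#' @param truth interval table of planted tissue-specific enhancers.
#' @return list with `sensitivity`, `precision`, `n_hits`, `n_returned`,
#'   `n_truth`.
#' @export
screen_performance <- function(atlas, ids, truth) {
  sel <- atlas[atlas$id %in% ids, , drop = FALSE]
  if (!nrow(truth))
    return(list(sensitivity = NA_real_, precision = NA_real_,
                n_hits = 0L, n_returned = nrow(sel), n_truth = 0L))
  truth_gr <- intervals_to_granges(truth[, c("chrom", "start", "end")])
  if (!nrow(sel))
    return(list(sensitivity = 0, precision = NA_real_, n_hits = 0L,
                n_returned = 0L, n_truth = nrow(truth)))
  sel_gr <- intervals_to_granges(sel[, c("chrom", "start", "end")])
  recovered <- IRanges::overlapsAny(truth_gr, sel_gr)
  correct <- IRanges::overlapsAny(sel_gr, truth_gr)
  list(sensitivity = mean(recovered), precision = mean(correct),
       n_hits = sum(recovered), n_returned = nrow(sel), n_truth = nrow(truth))
}
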