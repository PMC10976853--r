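#' Selection thresholds for candidate ranking
#'
#' The screen's qualitative criteria — few repeats, high conservation — need
#' numeric cutoffs to be operational; these defaults are deliberate choices,
#' both exposed for configuration.
#'
#' @param max_repeat_fraction maximum tolerated repeat-masked fraction.
#' @param min_conservation minimum mean conservation score.
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(max_repeat_fraction = 0.2,
                                 min_conservation = 0.5) {
  stopifnot(max_repeat_fraction >= 0, max_repeat_fraction <= 1,
            min_conservation >= 0, min_conservation <= 1)
  structure(list(max_repeat_fraction = max_repeat_fraction,
                 min_conservation = min_conservation),
            class = "selection_thresholds")
}

#' Repeat-masked fraction of intervals
#'
#' Fraction of interval bases overlapping repeat annotation, computed from a
#' repeat BED table and/or the soft-masked genome (lowercase bases). When both
#' sources are supplied they must agree exactly, which is asserted.
#'
#' @param intervals interval table.
#' @param repeats repeat interval table (e.g. `reference$repeats`), or `NULL`.
#' @param genome named character vector of soft-masked sequences, or `NULL`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
repeat_fraction <- function(intervals, repeats = NULL, genome = NULL) {
  if (is.null(repeats) && is.null(genome))
    stop("supply repeats and/or a soft-masked genome")
  from_bed <- from_fa <- NULL
  if (!is.null(genome)) {
    bad <- setdiff(unique(intervals$chrom), names(genome))
    if (length(bad))
      stop("chromosome absent from annotation: ", paste(bad, collapse = ", "))
    from_fa <- vapply(seq_len(nrow(intervals)), function(i) {
      s <- substr(genome[[intervals$chrom[i]]], intervals$start[i] + 1,
                  intervals$end[i])
      sum(strsplit(s, "")[[1]] %in% c("a", "c", "g", "t", "n")) /
        (intervals$end[i] - intervals$start[i])
    }, 0)
  }
  if (!is.null(repeats)) {
    iv_gr <- intervals_to_granges(intervals[, c("chrom", "start", "end")])
    from_bed <- if (nrow(repeats)) {
      rep_gr <- GenomicRanges::reduce(
        intervals_to_granges(repeats[, c("chrom", "start", "end")]))
      hits <- GenomicRanges::findOverlaps(iv_gr, rep_gr)
      ov <- GenomicRanges::width(IRanges::pintersect(
        iv_gr[S4Vectors::queryHits(hits)], rep_gr[S4Vectors::subjectHits(hits)]))
      out <- numeric(nrow(intervals))
      acc <- tapply(ov, S4Vectors::queryHits(hits), sum)
      out[as.integer(names(acc))] <- acc
      out / (intervals$end - intervals$start)
    } else numeric(nrow(intervals))
  }
  if (!is.null(from_bed) && !is.null(from_fa)) {
    stopifnot(max(abs(from_bed - from_fa)) < 1e-12)
    return(from_bed)
  }
  if (!is.null(from_bed)) from_bed else from_fa
}

#' Mean conservation over intervals
#'
#' Base-weighted mean of a `[0,1]`-valued piecewise-constant track over each
#' interval; bases not covered by the track count as score 0. The covered
#' fraction is returned as an attribute so sparse tracks are visible.
#'
#' @param intervals interval table.
#' @param track conservation table (`chrom`, `start`, `end`, `score`).
#' @return numeric vector of mean scores, with attribute `covered_fraction`.
#' @export
conservation_score <- function(intervals, track) {
  if (any(track$score < 0 | track$score > 1))
    stop("conservation values must lie in [0, 1]")
  iv_gr <- intervals_to_granges(intervals[, c("chrom", "start", "end")])
  tr_gr <- intervals_to_granges(track[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(iv_gr, tr_gr)
  ov <- GenomicRanges::width(IRanges::pintersect(
    iv_gr[S4Vectors::queryHits(hits)], tr_gr[S4Vectors::subjectHits(hits)]))
  len <- intervals$end - intervals$start
  total <- covered <- numeric(nrow(intervals))
  sc <- tapply(ov * track$score[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), sum)
  cv <- tapply(ov, S4Vectors::queryHits(hits), sum)
  total[as.integer(names(sc))] <- sc
  covered[as.integer(names(cv))] <- cv
  out <- total / len
  attr(out, "covered_fraction") <- covered / len
  out
}

#' Nearest gene by TSS distance
#'
#' Distance is measured from the enhancer midpoint (`(start + end) %/% 2`) to
#' the transcription start site: gene `start` on `+`, gene `end` on `-`
#' (0-based half-open). Minimized over genes on the same chromosome; ties go
#' to the smaller TSS coordinate. A midpoint inside a gene body is not
#' special-cased — the distance is still to the TSS.
#'
#' @param intervals interval table.
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return data frame (`gene_id`, `tss_distance_bp`, `no_gene_on_chrom`);
#'   rows on gene-less chromosomes carry `NA` and are flagged.
#' @export
nearest_gene <- function(intervals, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  mids <- (intervals$start + intervals$end) %/% 2
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    j <- which(genes$chrom == intervals$chrom[i])
    if (!length(j))
      return(data.frame(gene_id = NA_character_, tss_distance_bp = NA_real_,
                        no_gene_on_chrom = TRUE, stringsAsFactors = FALSE))
    d <- abs(mids[i] - tss[j])
    best <- j[d == min(d)]
    best <- best[which.min(tss[best])]
    data.frame(gene_id = genes$gene_id[best], tss_distance_bp = min(d),
               no_gene_on_chrom = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate and rank enhancer candidates
#'
#' Builds the candidate table for a set of screened atlas ids — target
#' z-score, repeat fraction, conservation, nearest gene — applies the
#' thresholds, and ranks: all passing candidates before any failing one;
#' within each block descending target z, then ascending repeat fraction,
#' then descending conservation, then id.
#'
#' @param ids atlas ids (e.g. from [unique_enhancers()]).
#' @param atlas the unified atlas.
#' @param z a [zscore_matrix()].
#' @param target target tissue.
#' @param repeats,genome repeat annotation (see [repeat_fraction()]).
#' @param conservation conservation track table.
#' @param genes gene table.
#' @param thresholds a [selection_thresholds()].
#' @return data frame of ranked candidates with per-filter pass flags.
#' @export
rank_candidates <- function(ids, atlas, z, target, repeats = NULL,
                            genome = NULL, conservation, genes,
                            thresholds = selection_thresholds()) {
  sel <- atlas[match(ids, atlas$id), , drop = FALSE]
  if (anyNA(sel$chrom)) stop("ids absent from atlas")
  cand <- data.frame(id = sel$id, chrom = sel$chrom, start = sel$start,
                     end = sel$end, z_target = z[sel$id, target],
                     stringsAsFactors = FALSE)
  cand$repeat_fraction <- repeat_fraction(sel, repeats = repeats, genome = genome)
  cons <- conservation_score(sel, conservation)
  cand$conservation <- as.numeric(cons)
  ng <- nearest_gene(sel, genes)
  cand$nearest_gene <- ng$gene_id
  cand$tss_distance_bp <- ng$tss_distance_bp
  cand$no_gene_on_chrom <- ng$no_gene_on_chrom
  cand$pass_repeat <- cand$repeat_fraction <= thresholds$max_repeat_fraction
  cand$pass_conservation <- cand$conservation >= thresholds$min_conservation
  cand$pass_all <- cand$pass_repeat & cand$pass_conservation
  ord <- order(-cand$pass_all, -cand$z_target, cand$repeat_fraction,
               -cand$conservation, cand$id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}
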