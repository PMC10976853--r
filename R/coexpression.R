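#' Read a histology cell-count table
#'
#' CSV with columns `animal_id`, `section_id`, `region`, `n_reporter`
#' (eGFP-positive cells), `n_marker` (marker-positive cells), `n_double`
#' (double-positive cells) and `marker_name`. Counts come from manual or
#' Neurolucida-style counting; this module only consumes them.
#'
#' @param path CSV file.
#' @return validated count table.
#' @export
read_count_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("animal_id", "section_id", "region", "marker_name"))
    if (col %in% names(tbl)) tbl[[col]] <- as.character(tbl[[col]])
  validate_count_table(tbl)
}

#' @rdname read_count_table
#' @param tbl count table data frame.
#' @export
validate_count_table <- function(tbl) {
  need <- c("animal_id", "section_id", "region", "n_reporter", "n_marker",
            "n_double", "marker_name")
  if (!all(need %in% names(tbl)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  cnt <- tbl[, c("n_reporter", "n_marker", "n_double")]
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers")
  if (any(tbl$n_double > pmin(tbl$n_reporter, tbl$n_marker)))
    stop("n_double cannot exceed n_reporter or n_marker")
  tbl
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)` on the proportion scale; `NA`s
#'   when `n = 0`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Co-expression percentages from cell counts
#'
#' Computes the two directions behind the histology pie charts: the
#' percentage of reporter-positive (eGFP+) cells that are marker-positive,
#' and the percentage of marker-positive cells that are reporter-positive.
#' `pooled` mode sums counts across all rows before dividing and attaches
#' Wilson 95% confidence intervals; `animal` and `section` modes compute
#' per-group percentages and additionally report their mean and SD across
#' groups. Zero denominators yield `NA` flagged as undefined, never 0.
#'
#' @param tbl a validated count table.
#' @param group_by `"pooled"`, `"animal"` or `"section"`.
#' @param conf confidence level for Wilson intervals.
#' @return list of class `coexpression_result` with elements `groups` (one
#'   row per group: counts, both percentages, Wilson CIs, undefined flags),
#'   `summary` (mean/SD across groups; `NULL` for pooled) and `group_by`.
#' @export
coexpression_stats <- function(tbl, group_by = c("pooled", "animal", "section"),
                               conf = 0.95) {
  group_by <- match.arg(group_by)
  tbl <- validate_count_table(tbl)
  key <- switch(group_by,
                pooled = rep("pooled", nrow(tbl)),
                animal = as.character(tbl$animal_id),
                section = paste(tbl$animal_id, tbl$section_id, sep = "/"))
  one <- function(sub, label) {
    R <- sum(sub$n_reporter); M <- sum(sub$n_marker); D <- sum(sub$n_double)
    rm_ci <- if (R > 0) wilson_ci(D, R, conf) * 100 else c(NA_real_, NA_real_)
    mr_ci <- if (M > 0) wilson_ci(D, M, conf) * 100 else c(NA_real_, NA_real_)
    data.frame(group = label, n_reporter = R, n_marker = M, n_double = D,
               pct_reporter_marker = if (R > 0) 100 * D / R else NA_real_,
               rm_ci_lower = rm_ci[1], rm_ci_upper = rm_ci[2],
               undefined_rm = R == 0,
               pct_marker_reporter = if (M > 0) 100 * D / M else NA_real_,
               mr_ci_lower = mr_ci[1], mr_ci_upper = mr_ci[2],
               undefined_mr = M == 0,
               stringsAsFactors = FALSE)
  }
  parts <- split(tbl, key)
  groups <- do.call(rbind, Map(one, parts, names(parts)))
  rownames(groups) <- NULL
  summary <- NULL
  if (group_by != "pooled") {
    summary <- data.frame(
      direction = c("pct_reporter_marker", "pct_marker_reporter"),
      mean = c(mean(groups$pct_reporter_marker, na.rm = TRUE),
               mean(groups$pct_marker_reporter, na.rm = TRUE)),
      sd = c(stats::sd(groups$pct_reporter_marker, na.rm = TRUE),
             stats::sd(groups$pct_marker_reporter, na.rm = TRUE)),
      n_groups = c(sum(!groups$undefined_rm), sum(!groups$undefined_mr)),
      stringsAsFactors = FALSE)
  }
  structure(list(groups = groups, summary = summary, group_by = group_by),
            class = "coexpression_result")
}
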