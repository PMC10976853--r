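#' Run the full enhancer screen on peak calls and coverage
#'
#' Convenience chain over the core modules: merge peaks into the unified
#' atlas, quantify and normalize signal, average per tissue, z-score across
#' tissues, and extract tissue-unique enhancers for every tissue group.
#'
#' @param peaksets named list of peak sets (by sample id).
#' @param coverages named list of coverage tables (by sample id).
#' @param sheet sample sheet.
#' @param z_min,max_ref_hits uniqueness gates (see [unique_enhancers()]).
#' @return list with `atlas`, `signal_raw`, `signal_norm`, `tissue_signal`,
#'   `zscores` and `unique_ids` (named list per tissue).
#' @export
run_screen <- function(peaksets, coverages, sheet, z_min = 2.0,
                       max_ref_hits = 0L) {
  validate_sample_sheet(sheet)
  atlas <- merge_peaks(peaksets)
  raw <- quantify_signal(atlas, coverages, sheet)
  norm <- normalize_signal(raw)
  tsig <- tissue_means(norm, sheet)
  z <- zscore_matrix(tsig)
  uniq <- lapply(unique(sheet$tissue), function(t)
    unique_enhancers(atlas, z, peaksets, sheet, t,
                     z_min = z_min, max_ref_hits = max_ref_hits))
  names(uniq) <- unique(sheet$tissue)
  list(atlas = atlas, signal_raw = raw, signal_norm = norm,
       tissue_signal = tsig, zscores = z, unique_ids = uniq)
}
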