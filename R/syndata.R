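#' Simulation configuration
#'
#' Defines the synthetic multi-tissue H3K27ac-like dataset: a small random
#' genome, soft-masked repeat runs, a conservation track, a gene table, and
#' planted enhancers (shared across all tissues, restricted to one tissue, or
#' repeat-overlapping decoys) whose activity drives negative-binomial binned
#' coverage per sample.
#'
#' Defaults describe the study conditions used throughout the package's tests:
#' a 2 Mb genome (2 chromosomes of 1 Mb) at 100 bp coverage resolution, five
#' brain-region tissue groups with two replicates each, 200 broadly active
#' enhancers, 50 tissue-restricted enhancers per tissue at 8-fold signal over
#' background, plus 5 repeat-overlapping decoys per tissue, with
#' negative-binomial dispersion 0.1.
#'
#' @param seed integer master seed; every generated artifact is a pure
#'   function of the configuration including this seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param bin_bp coverage bin width; must divide `chrom_length_bp`.
#' @param tissues character vector of tissue-group labels.
#' @param replicates_per_tissue samples per tissue group.
#' @param n_shared_enhancers enhancers active in every tissue.
#' @param n_specific_per_tissue enhancers active in exactly one tissue.
#' @param n_decoys_per_tissue additional tissue-restricted enhancers planted
#'   inside repeat runs, so the downstream repeat filter has true signal to
#'   remove. They count as genuinely active in their tissue.
#' @param enhancer_len_bp enhancer width; must be at least `bin_bp`.
#' @param fold_change mean active-enhancer signal over background (> 1).
#' @param background_mean expected background counts per bin.
#' @param dispersion negative-binomial dispersion alpha in
#'   `variance = mu + alpha * mu^2`; `0` selects the Poisson limit.
#' @param repeat_fraction_genome target fraction of soft-masked bases.
#' @param n_genes genes in the annotation table.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1000000L,
                       bin_bp = 100L,
                       tissues = c("vHC", "DG", "CA1", "mPFC", "MEC"),
                       replicates_per_tissue = 2L,
                       n_shared_enhancers = 200L,
                       n_specific_per_tissue = 50L,
                       n_decoys_per_tissue = 5L,
                       enhancer_len_bp = 500L,
                       fold_change = 8,
                       background_mean = 5,
                       dispersion = 0.1,
                       repeat_fraction_genome = 0.1,
                       n_genes = 100L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp), bin_bp = as.integer(bin_bp),
              tissues = as.character(tissues),
              replicates_per_tissue = as.integer(replicates_per_tissue),
              n_shared_enhancers = as.integer(n_shared_enhancers),
              n_specific_per_tissue = as.integer(n_specific_per_tissue),
              n_decoys_per_tissue = as.integer(n_decoys_per_tissue),
              enhancer_len_bp = as.integer(enhancer_len_bp),
              fold_change = fold_change, background_mean = background_mean,
              dispersion = dispersion,
              repeat_fraction_genome = repeat_fraction_genome,
              n_genes = as.integer(n_genes))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_bp >= 1, cfg$bin_bp >= 1,
            length(cfg$tissues) >= 1, cfg$replicates_per_tissue >= 1,
            cfg$n_shared_enhancers >= 0, cfg$n_specific_per_tissue >= 0,
            cfg$n_decoys_per_tissue >= 0, cfg$n_genes >= 1)
  if (cfg$fold_change <= 1) stop("fold_change must be > 1")
  if (cfg$background_mean <= 0) stop("background_mean must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$chrom_length_bp %% cfg$bin_bp != 0)
    stop("bin_bp must divide chrom_length_bp")
  if (cfg$enhancer_len_bp < cfg$bin_bp)
    stop("enhancer_len_bp must be >= bin_bp")
  if (cfg$repeat_fraction_genome < 0 || cfg$repeat_fraction_genome > 0.8)
    stop("repeat_fraction_genome must be in [0, 0.8]")
  if (anyDuplicated(cfg$tissues)) stop("tissue labels must be unique")
  n_enh <- cfg$n_shared_enhancers +
    length(cfg$tissues) * (cfg$n_specific_per_tissue + cfg$n_decoys_per_tissue)
  genome_bp <- cfg$n_chromosomes * cfg$chrom_length_bp
  if (n_enh * cfg$enhancer_len_bp > 0.5 * genome_bp)
    stop("planted features cannot fit: total enhancer bases exceed 50% of the genome")
  invisible(cfg)
}

# Enhancers (and repeat runs) are laid out on a fixed grid of slots of width
# 2 x enhancer_len_bp rounded up to a bin multiple.  One feature per slot,
# anchored at the slot start, guarantees non-overlap and an inter-enhancer gap
# of at least enhancer_len_bp, with bin-aligned starts.
slot_grid <- function(cfg) {
  w <- ceiling(2 * cfg$enhancer_len_bp / cfg$bin_bp) * cfg$bin_bp
  per_chrom <- cfg$chrom_length_bp %/% w
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  data.frame(chrom = rep(chroms, each = per_chrom),
             start = rep(w * (seq_len(per_chrom) - 1), cfg$n_chromosomes),
             width = w, stringsAsFactors = FALSE)
}

#' Generate the synthetic reference bundle
#'
#' Builds a random genome with soft-masked (lowercase) repeat runs, the
#' matching repeat BED, a per-bin conservation track with Beta(1,4) background
#' values, and a random gene table. Deterministic for a fixed configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `edge_reference` with elements `genome` (named
#'   character vector, soft-masked), `repeats` (interval table),
#'   `conservation` (interval table with `score` in `[0,1]`), `genes`
#'   (gene table) and `config`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "reference"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp

  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(genome_chars) <- chroms

  # repeat runs inside grid slots (sub-slot length keeps runs non-adjacent)
  slots <- slot_grid(config)
  target_bp <- round(config$repeat_fraction_genome * config$n_chromosomes * L)
  rep_list <- list()
  if (target_bp > 0) {
    ord <- sample.int(nrow(slots))
    run_min <- min(200L, slots$width[1] - config$bin_bp)
    run_max <- slots$width[1] - config$bin_bp
    total <- 0
    for (i in ord) {
      if (total >= target_bp) break
      len <- if (run_min >= run_max) run_min else
        sample(seq(run_min, run_max), 1)
      len <- min(len, max(run_min, target_bp - total))
      rep_list[[length(rep_list) + 1]] <-
        data.frame(chrom = slots$chrom[i], start = slots$start[i],
                   end = slots$start[i] + len, slot = i,
                   stringsAsFactors = FALSE)
      total <- total + len
    }
  }
  repeats <- if (length(rep_list)) sort_intervals(do.call(rbind, rep_list))
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric(), slot = integer())
  rownames(repeats) <- NULL
  for (i in seq_len(nrow(repeats))) {
    ch <- repeats$chrom[i]
    idx <- (repeats$start[i] + 1):repeats$end[i]
    genome_chars[[ch]][idx] <- tolower(genome_chars[[ch]][idx])
  }
  genome <- vapply(genome_chars, paste, "", collapse = "")

  # per-bin conservation background, Beta(1,4)
  nbin <- L %/% config$bin_bp
  cons <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = config$bin_bp * (seq_len(nbin) - 1),
               end = config$bin_bp * seq_len(nbin),
               score = round(stats::rbeta(nbin, 1, 4), 4),
               stringsAsFactors = FALSE)))

  glen <- pmin(sample(2000:10000, config$n_genes, replace = TRUE), L %/% 2)
  gchrom <- sample(chroms, config$n_genes, replace = TRUE)
  gstart <- vapply(glen, function(l) sample.int(L - l, 1) - 1, 0)
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
                      chrom = gchrom, start = gstart, end = gstart + glen,
                      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)

  structure(list(genome = genome, repeats = repeats, conservation = cons,
                 genes = genes, config = config),
            class = "edge_reference")
}

#' Plant ground-truth enhancers
#'
#' Places shared, tissue-specific and decoy enhancers on the slot grid:
#' non-overlapping, bin-aligned, each at least one enhancer length from its
#' neighbor. Decoys are planted at repeat-run starts so they overlap masked
#' sequence; shared and tissue-specific enhancers avoid repeat slots entirely.
#' Tissue-specific enhancers are flagged conserved (their conservation-track
#' bins are elevated by [elevate_conservation()]); decoys are not.
#'
#' @param reference an `edge_reference` built with the same `config`.
#' @param config the [sim_config()].
#' @return data frame of class `planted_enhancers`: `chrom`, `start`, `end`,
#'   `id`, `kind` (`"shared"`/`"tissue_specific"`), `tissue` (`NA` for
#'   shared), `decoy`, `conserved`, `repeat_overlap`.
#' @export
plant_enhancers <- function(reference, config) {
  stopifnot(inherits(reference, "edge_reference"))
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "enhancers"))
  slots <- slot_grid(config)
  n_t <- length(config$tissues)
  repeat_slots <- reference$repeats$slot
  free_slots <- setdiff(seq_len(nrow(slots)), repeat_slots)

  n_clean <- config$n_shared_enhancers + n_t * config$n_specific_per_tissue
  n_decoy <- n_t * config$n_decoys_per_tissue
  if (length(free_slots) < n_clean)
    stop("enhancer placement failed: not enough repeat-free slots (need ",
         n_clean, ", have ", length(free_slots), ")")
  if (length(repeat_slots) < n_decoy)
    stop("enhancer placement failed: not enough repeat slots for decoys (need ",
         n_decoy, ", have ", length(repeat_slots), ")")

  pick_clean <- free_slots[sample.int(length(free_slots), n_clean)]
  pick_decoy <- if (n_decoy > 0)
    repeat_slots[sample.int(length(repeat_slots), n_decoy)] else integer()

  kind <- c(rep("shared", config$n_shared_enhancers),
            rep("tissue_specific", n_t * config$n_specific_per_tissue),
            rep("tissue_specific", n_decoy))
  tissue <- c(rep(NA_character_, config$n_shared_enhancers),
              rep(config$tissues, each = config$n_specific_per_tissue),
              rep(config$tissues, each = config$n_decoys_per_tissue))
  decoy <- c(rep(FALSE, n_clean), rep(TRUE, n_decoy))
  slot_idx <- c(pick_clean, pick_decoy)

  enh <- data.frame(chrom = slots$chrom[slot_idx],
                    start = slots$start[slot_idx],
                    end = slots$start[slot_idx] + config$enhancer_len_bp,
                    kind = kind, tissue = tissue, decoy = decoy,
                    stringsAsFactors = FALSE)
  enh$conserved <- enh$kind == "tissue_specific" & !enh$decoy
  rep_by_slot <- stats::setNames(reference$repeats$end - reference$repeats$start,
                                 reference$repeats$slot)
  ov <- pmin(as.numeric(rep_by_slot[as.character(slot_idx)]), config$enhancer_len_bp)
  enh$repeat_overlap <- ifelse(enh$decoy, ov / config$enhancer_len_bp, 0)
  enh <- sort_intervals(enh)
  rownames(enh) <- NULL
  enh$id <- sprintf("enh%04d", seq_len(nrow(enh)))
  class(enh) <- c("planted_enhancers", "data.frame")
  enh
}

#' Activity matrix of planted enhancers
#' @param enhancers output of [plant_enhancers()].
#' @param tissues tissue labels.
#' @return logical matrix enhancers x tissues.
#' @export
enhancer_activity <- function(enhancers, tissues) {
  act <- vapply(tissues, function(t)
    enhancers$kind == "shared" | enhancers$tissue %in% t,
    logical(nrow(enhancers)))
  rownames(act) <- enhancers$id
  act
}

#' Ground-truth intervals for one tissue
#'
#' The tissue-restricted truth: enhancers (decoys included) active in exactly
#' this tissue, i.e. the set the specificity screen should recover.
#' @param enhancers output of [plant_enhancers()].
#' @param tissue tissue label.
#' @return interval table.
#' @export
truth_intervals <- function(enhancers, tissue) {
  out <- enhancers[enhancers$kind == "tissue_specific" &
                     !is.na(enhancers$tissue) & enhancers$tissue == tissue,
                   c("chrom", "start", "end", "id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Elevate conservation over conserved enhancers
#'
#' Replaces the Beta(1,4) background values of bins overlapping an enhancer
#' flagged `conserved` with Beta(8,2) draws, giving the conservation filter a
#' usable separation.
#' @param reference an `edge_reference`.
#' @param enhancers output of [plant_enhancers()].
#' @return the reference with an updated conservation track.
#' @export
elevate_conservation <- function(reference, enhancers) {
  cons <- reference$conservation
  keep <- enhancers[enhancers$conserved, , drop = FALSE]
  if (nrow(keep)) {
    set.seed(derive_seed(reference$config$seed, "conservation"))
    mid_in <- bins_in_intervals(cons, keep)
    cons$score[mid_in] <- round(stats::rbeta(sum(mid_in), 8, 2), 4)
    reference$conservation <- cons
  }
  reference
}

#' Which bins lie inside a set of intervals
#'
#' A bin counts as inside when its midpoint falls within an interval; with the
#' generator's bin-aligned enhancers this equals full containment.
#' @param bins interval table of uniform bins.
#' @param intervals interval table.
#' @return logical vector along `bins`.
#' @export
bins_in_intervals <- function(bins, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, nrow(bins)))
  mids <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(
    (bins$start + bins$end) %/% 2 + 1, width = 1))
  IRanges::overlapsAny(mids, intervals_to_granges(intervals[, c("chrom", "start", "end")]))
}

#' Build the default sample sheet for a configuration
#' @param config a [sim_config()].
#' @return sample sheet data frame (`sample_id`, `tissue`, `replicate`).
#' @export
sim_sample_sheet <- function(config) {
  data.frame(
    sample_id = paste0(rep(config$tissues, each = config$replicates_per_tissue),
                       "_r", seq_len(config$replicates_per_tissue)),
    tissue = rep(config$tissues, each = config$replicates_per_tissue),
    replicate = rep(seq_len(config$replicates_per_tissue), length(config$tissues)),
    stringsAsFactors = FALSE)
}

#' Simulate per-sample binned coverage
#'
#' Each bin's count is negative-binomial with mean `background_mean`, or
#' `fold_change * background_mean` for bins inside an enhancer active in that
#' sample's tissue (`variance = mu + dispersion * mu^2`; `dispersion = 0`
#' falls back to Poisson). Each sample is seeded independently from the master
#' seed and its `sample_id`, so a sample's track does not depend on which
#' other samples are simulated.
#'
#' @param reference an `edge_reference`.
#' @param enhancers output of [plant_enhancers()].
#' @param sample_sheet rows of (`sample_id`, `tissue`, `replicate`).
#' @param config the [sim_config()].
#' @return named list (by `sample_id`) of coverage tables
#'   (`chrom`, `start`, `end`, `count`).
#' @export
simulate_coverage <- function(reference, enhancers, sample_sheet, config) {
  validate_sample_sheet(sample_sheet)
  unknown <- setdiff(sample_sheet$tissue, config$tissues)
  if (length(unknown))
    stop("unknown tissue label in sample sheet: ", paste(unknown, collapse = ", "))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  nbin <- config$chrom_length_bp %/% config$bin_bp
  bins <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = config$bin_bp * (seq_len(nbin) - 1),
               end = config$bin_bp * seq_len(nbin), stringsAsFactors = FALSE)))

  active_by_tissue <- lapply(config$tissues, function(t) {
    act <- enhancers[enhancers$kind == "shared" |
                       (!is.na(enhancers$tissue) & enhancers$tissue == t), , drop = FALSE]
    bins_in_intervals(bins, act)
  })
  names(active_by_tissue) <- config$tissues

  out <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    sid <- sample_sheet$sample_id[i]
    set.seed(derive_seed(config$seed, "coverage", sid))
    mu <- rep(config$background_mean, nrow(bins))
    mu[active_by_tissue[[sample_sheet$tissue[i]]]] <-
      config$fold_change * config$background_mean
    cnt <- if (config$dispersion == 0) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    cbind(bins, count = cnt)
  })
  names(out) <- sample_sheet$sample_id
  out
}

#' Toy threshold peak caller
#'
#' A deliberately simple stand-in for a real peak caller, used only on
#' synthetic coverage: a bin qualifies when its count reaches `min_fold` times
#' the genome-wide median bin count; adjacent qualifying bins merge and merged
#' runs shorter than `min_width_bp` are dropped. All-zero coverage yields an
#' empty peak set.
#'
#' @param coverage a coverage table with uniform bin width.
#' @param min_fold multiple of the genome-wide median count a bin must reach.
#' @param min_width_bp minimum merged peak width kept.
#' @param sample_id label for the resulting peak set.
#' @return a [peak_set()] (sorted interval table).
#' @export
call_toy_peaks <- function(coverage, min_fold = 4, min_width_bp = 200,
                           sample_id = "sample") {
  widths <- unique(coverage$end - coverage$start)
  if (length(widths) != 1)
    stop("coverage bins must have uniform width")
  empty <- genomic_intervals(character(), integer(), integer())
  if (!nrow(coverage) || all(coverage$count == 0))
    return(peak_set(empty, sample_id))
  thr <- min_fold * stats::median(coverage$count)
  cov <- sort_intervals(coverage)
  res <- lapply(split(cov, cov$chrom), function(cc) {
    q <- cc$count >= thr
    r <- rle(q)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values & (r$lengths * widths >= min_width_bp)
    if (!any(keep)) return(NULL)
    data.frame(chrom = cc$chrom[1], start = cc$start[starts[keep]],
               end = cc$end[ends[keep]], stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  peaks <- if (length(res)) do.call(rbind, res) else empty
  peak_set(peaks, sample_id)
}

#' Simulate a complete dataset
#'
#' Orchestrates [generate_reference()], [plant_enhancers()],
#' [elevate_conservation()], [simulate_coverage()] and [call_toy_peaks()] and
#' optionally writes every artifact (genome.fa, repeats.bed,
#' conservation.bedgraph, genes.tsv, per-sample bedGraph and peak BED,
#' truth/<tissue>.bed, sample_sheet.csv) to a directory.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @param min_fold,min_width_bp toy peak-caller settings.
#' @return list with `reference`, `enhancers`, `sheet`, `coverage` (named
#'   list), `peaks` (named list of peak sets), `truth` (named list of interval
#'   tables per tissue) and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL,
                             min_fold = 4, min_width_bp = 200) {
  ref <- generate_reference(config)
  enh <- plant_enhancers(ref, config)
  ref <- elevate_conservation(ref, enh)
  sheet <- sim_sample_sheet(config)
  cov <- simulate_coverage(ref, enh, sheet, config)
  peaks <- lapply(names(cov), function(sid)
    call_toy_peaks(cov[[sid]], min_fold, min_width_bp, sample_id = sid))
  names(peaks) <- names(cov)
  truth <- lapply(config$tissues, function(t) truth_intervals(enh, t))
  names(truth) <- config$tissues

  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(ref$genome, file.path(dir, "genome.fa"))
    write_bed(ref$repeats, file.path(dir, "repeats.bed"))
    cons <- ref$conservation; names(cons)[names(cons) == "score"] <- "count"
    write_bedgraph(cons, file.path(dir, "conservation.bedgraph"))
    write_gene_table(ref$genes, file.path(dir, "genes.tsv"))
    write_sample_sheet(sheet, file.path(dir, "sample_sheet.csv"))
    for (sid in names(cov)) {
      write_bedgraph(cov[[sid]], file.path(dir, paste0(sid, ".bedgraph")))
      write_bed(peaks[[sid]], file.path(dir, paste0(sid, ".peaks.bed")))
    }
    for (t in names(truth)) write_bed(truth[[t]], file.path(dir, "truth", paste0(t, ".bed")))
    enh_out <- enh; class(enh_out) <- "data.frame"
    utils::write.table(enh_out, file.path(dir, "planted_enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reference = ref, enhancers = enh, sheet = sheet, coverage = cov,
       peaks = peaks, truth = truth, config = config)
}
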