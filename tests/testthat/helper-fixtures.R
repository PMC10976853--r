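# Shared fixtures: a small fast dataset for unit tests and the full default
# study-condition dataset (memoized; simulated once per test run).

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11L) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length_bp = 100000L,
             bin_bp = 100L, tissues = c("A", "B", "C"),
             replicates_per_tissue = 2L, n_shared_enhancers = 10L,
             n_specific_per_tissue = 6L, n_decoys_per_tissue = 2L,
             enhancer_len_bp = 500L, fold_change = 8, background_mean = 5,
             dispersion = 0.1, repeat_fraction_genome = 0.1, n_genes = 20L)
}

small_dataset <- function() {
  if (is.null(.fixture_cache$small)) .fixture_cache$small <-
      simulate_dataset(small_config())
  .fixture_cache$small
}

default_dataset <- function() {
  if (is.null(.fixture_cache$default)) .fixture_cache$default <-
      simulate_dataset(sim_config(seed = 7L))
  .fixture_cache$default
}

default_screen <- function(z_min = 1.5) {
  key <- paste0("screen_", z_min)
  if (is.null(.fixture_cache[[key]])) {
    ds <- default_dataset()
    .fixture_cache[[key]] <- run_screen(ds$peaks, ds$coverage, ds$sheet,
                                        z_min = z_min)
  }
  .fixture_cache[[key]]
}

random_intervals <- function(n, max_coord = 10000, chroms = "chr1",
                             min_len = 1, max_len = 400) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# fuse bookended (touching) intervals; the boolean-mask view of an atlas
fuse_bookended <- function(df) {
  gr <- GenomicRanges::reduce(intervals_to_granges(df[, c("chrom", "start", "end")]))
  out <- granges_to_intervals(GenomicRanges::sort(gr))
  rownames(out) <- NULL
  out
}

# draws a random enhancer free of EcoRI/SalI sites
random_site_free_dna <- function(n) {
  repeat {
    s <- random_dna(n)
    if (!nrow(check_internal_sites(s))) return(s)
  }
}
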