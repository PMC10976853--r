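test_that("config validation rejects impossible setups", {
  expect_error(sim_config(fold_change = 1), "fold_change")
  expect_error(sim_config(bin_bp = 300), "divide")
  expect_error(sim_config(enhancer_len_bp = 50), "enhancer_len_bp")
  # planted bases exceeding half the genome
  expect_error(sim_config(n_chromosomes = 1, chrom_length_bp = 100000,
                          n_shared_enhancers = 200, n_specific_per_tissue = 0,
                          n_decoys_per_tissue = 0, enhancer_len_bp = 500),
               "cannot fit")
})

test_that("reference generation is deterministic and masks the right fraction", {
  cfg <- small_config(seed = 7)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$repeats, r2$repeats)
  expect_identical(r1$conservation, r2$conservation)
  expect_identical(r1$genes, r2$genes)

  # independent per-base scan: lowercase bases vs repeat BED, exact agreement
  chars <- strsplit(r1$genome, "")
  n_lower <- sum(vapply(chars, function(ch) sum(ch %in% letters), 0L))
  expect_equal(n_lower, sum(r1$repeats$end - r1$repeats$start))
  for (i in seq_len(nrow(r1$repeats))) {
    ch <- chars[[r1$repeats$chrom[i]]]
    idx <- (r1$repeats$start[i] + 1):r1$repeats$end[i]
    expect_true(all(ch[idx] %in% letters))
    if (r1$repeats$end[i] < length(ch))
      expect_false(ch[r1$repeats$end[i] + 1] %in% letters)
  }

  genome_bp <- cfg$n_chromosomes * cfg$chrom_length_bp
  expect_lt(abs(n_lower / genome_bp - cfg$repeat_fraction_genome), 0.05)
  expect_true(all(r1$conservation$score >= 0 & r1$conservation$score <= 1))
  expect_true(all(r1$genes$strand %in% c("+", "-")))
})

test_that("zero repeat fraction gives an all-uppercase genome and empty BED", {
  cfg <- small_config()
  cfg$repeat_fraction_genome <- 0
  r <- generate_reference(cfg)
  expect_equal(nrow(r$repeats), 0)
  expect_false(any(grepl("[acgt]", r$genome)))
})

test_that("planted enhancers respect bookkeeping, spacing and activity", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length_bp = 100000,
                    tissues = c("A", "B"), n_shared_enhancers = 2,
                    n_specific_per_tissue = 3, n_decoys_per_tissue = 0,
                    n_genes = 5)
  ref <- generate_reference(cfg)
  enh <- plant_enhancers(ref, cfg)
  expect_equal(nrow(enh), 8)
  act <- enhancer_activity(enh, cfg$tissues)
  expect_equal(sum(act[, "A"] & !act[, "B"]), 3)
  expect_equal(sum(act[, "B"] & !act[, "A"]), 3)
  expect_equal(sum(act[, "A"] & act[, "B"]), 2)

  # brute-force all-pairs overlap and spacing check
  for (i in seq_len(nrow(enh))) for (j in seq_len(nrow(enh))) {
    if (i >= j || enh$chrom[i] != enh$chrom[j]) next
    gap <- max(enh$start[i], enh$start[j]) - min(enh$end[i], enh$end[j])
    expect_gte(gap, cfg$enhancer_len_bp)
  }
})

test_that("with no specific enhancers everything is shared", {
  cfg <- small_config()
  cfg$n_specific_per_tissue <- 0L
  cfg$n_decoys_per_tissue <- 0L
  ref <- generate_reference(cfg)
  enh <- plant_enhancers(ref, cfg)
  expect_true(all(enh$kind == "shared"))
  expect_equal(nrow(truth_intervals(enh, "A")), 0)
})

test_that("decoys overlap repeat runs; specific enhancers are conserved", {
  ds <- small_dataset()
  enh <- ds$enhancers
  expect_true(all(enh$repeat_overlap[enh$decoy] > 0))
  expect_true(all(enh$repeat_overlap[!enh$decoy] == 0))
  expect_true(all(enh$conserved[enh$kind == "tissue_specific" & !enh$decoy]))
  # decoys really sit on masked sequence
  rf <- repeat_fraction(enh[enh$decoy, ], repeats = ds$reference$repeats,
                        genome = ds$reference$genome)
  expect_true(all(rf > 0))
})

test_that("coverage follows the configured negative-binomial means", {
  ds <- default_dataset()
  cfg <- ds$config
  t1 <- cfg$tissues[1]
  cov <- ds$coverage[[paste0(t1, "_r1")]]
  active <- bins_in_intervals(
    cov, ds$enhancers[ds$enhancers$kind == "shared" |
                        (!is.na(ds$enhancers$tissue) & ds$enhancers$tissue == t1), ])
  mu_active <- cfg$fold_change * cfg$background_mean
  n <- sum(active)
  expect_gte(n, 500)
  se <- sqrt(mu_active * (1 + cfg$dispersion * mu_active) / n)
  expect_lt(abs(mean(cov$count[active]) - mu_active), 3 * se)
  se_bg <- sqrt(cfg$background_mean * (1 + cfg$dispersion * cfg$background_mean) /
                  sum(!active))
  expect_lt(abs(mean(cov$count[!active]) - cfg$background_mean), 3 * se_bg)
  expect_true(all(cov$count >= 0 & cov$count == round(cov$count)))
})

test_that("signal contrast matches the configured fold change", {
  ds <- default_dataset()
  cfg <- ds$config
  ratios <- vapply(cfg$tissues, function(t) {
    cov <- ds$coverage[[paste0(t, "_r1")]]
    active <- bins_in_intervals(
      cov, ds$enhancers[ds$enhancers$kind == "shared" |
                          (!is.na(ds$enhancers$tissue) & ds$enhancers$tissue == t), ])
    mean(cov$count[active]) / mean(cov$count[!active])
  }, 0)
  expect_true(all(ratios >= 0.8 * cfg$fold_change))
  expect_true(all(ratios <= 1.2 * cfg$fold_change))
})

test_that("dispersion zero falls back to Poisson (variance ~ mean)", {
  cfg <- small_config()
  cfg$dispersion <- 0
  ref <- generate_reference(cfg)
  enh <- plant_enhancers(ref, cfg)
  sheet <- sim_sample_sheet(cfg)
  cov <- simulate_coverage(ref, enh, sheet, cfg)[["A_r1"]]
  bg <- !bins_in_intervals(cov, enh)
  m <- mean(cov$count[bg]); v <- stats::var(cov$count[bg])
  expect_lt(abs(v / m - 1), 0.15)
})

test_that("coverage is reproducible per sample and rejects unknown tissues", {
  cfg <- small_config()
  ref <- generate_reference(cfg)
  enh <- plant_enhancers(ref, cfg)
  sheet <- sim_sample_sheet(cfg)
  c1 <- simulate_coverage(ref, enh, sheet, cfg)
  c2 <- simulate_coverage(ref, enh, sheet[2:1, ], cfg)
  expect_identical(c1[["A_r2"]], c2[["A_r2"]])
  bad <- sheet; bad$tissue[1] <- "nonexistent"
  expect_error(simulate_coverage(ref, enh, bad, cfg), "unknown tissue")
})

test_that("toy peak caller thresholds, merges and filters as documented", {
  cov <- data.frame(chrom = "chr1", start = seq(0, 400, 100),
                    end = seq(100, 500, 100), count = c(5, 5, 60, 64, 5))
  pk <- call_toy_peaks(cov, min_fold = 4, min_width_bp = 200)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 200)
  expect_equal(pk$end, 400)

  # min_fold 0: every bin qualifies, one peak per chromosome
  cov2 <- rbind(cov, transform(cov, chrom = "chr2"))
  pk2 <- call_toy_peaks(cov2, min_fold = 0, min_width_bp = 100)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$start, c(0, 0))
  expect_equal(pk2$end, c(500, 500))

  # min_width larger than any run
  expect_equal(nrow(call_toy_peaks(cov, min_fold = 4, min_width_bp = 300)), 0)
  # all-zero coverage is empty, not an error
  cov0 <- transform(cov, count = 0)
  expect_equal(nrow(call_toy_peaks(cov0, min_fold = 0, min_width_bp = 100)), 0)
  # non-uniform bins rejected
  bad <- cov; bad$end[2] <- 250
  expect_error(call_toy_peaks(bad), "uniform")
})

test_that("toy peaks recover planted active enhancers per sample", {
  ds <- default_dataset()
  for (sid in c("vHC_r1", "DG_r1", "MEC_r2")) {
    t <- sub("_r[0-9]+$", "", sid)
    act <- ds$enhancers[ds$enhancers$kind == "shared" |
                          (!is.na(ds$enhancers$tissue) & ds$enhancers$tissue == t), ]
    hit <- IRanges::overlapsAny(
      intervals_to_granges(act[, c("chrom", "start", "end")]),
      intervals_to_granges(as.data.frame(ds$peaks[[sid]])))
    expect_gte(mean(hit), 0.95)
  }
})

test_that("simulate_dataset writes the full artifact bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_config()
  ds <- simulate_dataset(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "repeats.bed", "conservation.bedgraph", "genes.tsv",
    "sample_sheet.csv", "A_r1.bedgraph", "A_r1.peaks.bed",
    file.path("truth", "A.bed"))))))
  # round trips
  g <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(g, ds$reference$genome)
  cov <- read_bedgraph(file.path(dir, "A_r1.bedgraph"))
  expect_equal(sum(cov$count), sum(ds$coverage$A_r1$count))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  expect_equal(sheet, ds$sheet)
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes, ds$reference$genes)
})
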