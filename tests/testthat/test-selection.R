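test_that("repeat fraction from BED matches hand cases and the FASTA scan", {
  iv <- genomic_intervals("chr1", 0, 100)
  reps <- genomic_intervals("chr1", 50, 150)
  expect_equal(repeat_fraction(iv, repeats = reps), 0.5)
  expect_equal(repeat_fraction(iv, repeats = reps[0, ]), 0)

  # 20 random intervals: BED route vs independent lowercase-count oracle
  ds <- small_dataset()
  set.seed(19)
  iv20 <- random_intervals(20, max_coord = ds$config$chrom_length_bp,
                           chroms = c("chr1", "chr2"), min_len = 100,
                           max_len = 2000)
  got <- repeat_fraction(iv20, repeats = ds$reference$repeats)
  oracle <- vapply(seq_len(20), function(i) {
    s <- substr(ds$reference$genome[[iv20$chrom[i]]], iv20$start[i] + 1, iv20$end[i])
    mean(strsplit(s, "")[[1]] %in% letters)
  }, 0)
  expect_equal(got, oracle, tolerance = 1e-12)
  # dual-source call agrees with itself by assertion
  both <- repeat_fraction(iv20, repeats = ds$reference$repeats,
                          genome = ds$reference$genome)
  expect_equal(both, oracle, tolerance = 1e-12)
  expect_error(repeat_fraction(genomic_intervals("chrZ", 0, 10),
                               genome = ds$reference$genome), "chrZ")
})

test_that("conservation score is a base-weighted mean with uncovered = 0", {
  iv <- genomic_intervals("chr1", 100, 300)
  uniform <- data.frame(chrom = "chr1", start = c(100, 200),
                        end = c(200, 300), score = 0.8)
  expect_equal(as.numeric(conservation_score(iv, uniform)), 0.8)

  half <- data.frame(chrom = "chr1", start = 100, end = 200, score = 1)
  sc <- conservation_score(iv, half)
  expect_equal(as.numeric(sc), 0.5)
  expect_equal(attr(sc, "covered_fraction"), 0.5)

  expect_error(conservation_score(iv, transform(half, score = 1.2)), "\\[0, 1\\]")

  # random piecewise track vs per-base averaging oracle
  set.seed(23)
  for (rep in 1:20) {
    track <- data.frame(chrom = "chr1", start = 50 * 0:39, end = 50 * 1:40,
                        score = round(stats::runif(40), 3))
    track <- track[stats::runif(40) > 0.3, ]  # punch holes
    ivr <- random_intervals(5, max_coord = 2000, min_len = 10, max_len = 900)
    got <- as.numeric(conservation_score(ivr, track))
    base <- numeric(2000)
    for (i in seq_len(nrow(track)))
      base[(track$start[i] + 1):track$end[i]] <- track$score[i]
    oracle <- vapply(seq_len(nrow(ivr)), function(i)
      mean(base[(ivr$start[i] + 1):ivr$end[i]]), 0)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("nearest gene uses strand-aware TSS and midpoint distance", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(400, 1800), end = c(900, 2400),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  iv <- genomic_intervals("chr1", 900, 1100)  # midpoint 1000
  ng <- nearest_gene(iv, genes)
  expect_equal(ng$gene_id, "g1")
  expect_equal(ng$tss_distance_bp, 600)

  # '-' strand gene [2000,3000): TSS at 3000
  gneg <- data.frame(gene_id = "g3", chrom = "chr1", start = 2000, end = 3000,
                     strand = "-", stringsAsFactors = FALSE)
  ng2 <- nearest_gene(genomic_intervals("chr1", 3090, 3110), gneg)
  expect_equal(ng2$tss_distance_bp, 100)

  # tie broken toward the smaller TSS coordinate
  gt <- data.frame(gene_id = c("far", "near_lo", "near_hi"), chrom = "chr1",
                   start = c(9000, 500, 1500), end = c(9500, 800, 2000),
                   strand = "+", stringsAsFactors = FALSE)
  ngt <- nearest_gene(genomic_intervals("chr1", 950, 1050), gt)
  expect_equal(ngt$gene_id, "near_lo")

  # gene-less chromosome flagged, not an error
  ngx <- nearest_gene(genomic_intervals("chr9", 0, 10), genes)
  expect_true(ngx$no_gene_on_chrom)
  expect_true(is.na(ngx$gene_id))
})

test_that("nearest gene agrees with an exhaustive all-pairs oracle", {
  set.seed(29)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      start = sample.int(90000, 20),
                      strand = sample(c("+", "-"), 20, TRUE),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(1000:5000, 20)
  iv <- random_intervals(50, max_coord = 95000, chroms = c("chr1", "chr2"))
  got <- nearest_gene(iv, genes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  for (i in seq_len(50)) {
    mid <- (iv$start[i] + iv$end[i]) %/% 2
    j <- which(genes$chrom == iv$chrom[i])
    d <- abs(mid - tss[j])
    expect_equal(got$tss_distance_bp[i], min(d))
    cand <- j[d == min(d)]
    expect_equal(got$gene_id[i], genes$gene_id[cand[which.min(tss[cand])]])
  }
})

test_that("ranking puts passing candidates first with the documented key", {
  ds <- small_dataset()
  scr <- run_screen(ds$peaks, ds$coverage, ds$sheet, z_min = 1.0)
  ids <- scr$unique_ids[["A"]]
  cand <- rank_candidates(ids, scr$atlas, scr$zscores, "A",
                          repeats = ds$reference$repeats,
                          genome = ds$reference$genome,
                          conservation = ds$reference$conservation,
                          genes = ds$reference$genes)
  expect_equal(cand$rank, seq_len(nrow(cand)))
  # block order: no failing candidate before a passing one
  expect_true(all(diff(cand$pass_all) <= 0))
  # within blocks, descending z
  for (blk in split(cand, cand$pass_all))
    expect_true(all(diff(blk$z_target) <= 1e-12))
  # independent comparison sort with the stated key
  key_order <- order(-cand$pass_all, -cand$z_target, cand$repeat_fraction,
                     -cand$conservation, cand$id)
  expect_equal(key_order, seq_len(nrow(cand)))
  # permutation invariance
  cand2 <- rank_candidates(sample(ids), scr$atlas, scr$zscores, "A",
                           repeats = ds$reference$repeats,
                           conservation = ds$reference$conservation,
                           genes = ds$reference$genes)
  expect_equal(cand2$id, cand$id)
})

test_that("repeat decoys fail the repeat filter; clean candidates pass", {
  ds <- small_dataset()
  scr <- run_screen(ds$peaks, ds$coverage, ds$sheet, z_min = 1.0)
  ids <- scr$unique_ids[["B"]]
  cand <- rank_candidates(ids, scr$atlas, scr$zscores, "B",
                          repeats = ds$reference$repeats,
                          conservation = ds$reference$conservation,
                          genes = ds$reference$genes)
  decoys <- ds$enhancers[ds$enhancers$decoy & ds$enhancers$tissue == "B", ]
  decoy_gr <- intervals_to_granges(decoys[, c("chrom", "start", "end")])
  cand_gr <- intervals_to_granges(cand[, c("chrom", "start", "end")])
  is_decoy <- IRanges::overlapsAny(cand_gr, decoy_gr)
  expect_true(all(!cand$pass_repeat[is_decoy]))
  # top of the list excludes every decoy
  n_pass <- sum(cand$pass_all)
  expect_gt(n_pass, 0)
  expect_true(all(!is_decoy[seq_len(n_pass)]))
  # planted conserved specific enhancers pass conservation
  expect_gte(mean(cand$pass_conservation[!is_decoy]), 0.9)
})

test_that("two candidates, equal z: repeat content decides rank and flags", {
  atlas <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(500, 1500),
                      id = c("c1", "c2"), stringsAsFactors = FALSE)
  z <- rbind(c1 = c(3, -1), c2 = c(3, -1)); colnames(z) <- c("A", "B")
  reps <- genomic_intervals("chr1", 1000, 1200)  # 0.4 of c2
  cons <- data.frame(chrom = "chr1", start = 0, end = 2000, score = 0.9)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000, end = 6000,
                      strand = "+", stringsAsFactors = FALSE)
  cand <- rank_candidates(c("c1", "c2"), atlas, z, "A", repeats = reps,
                          conservation = cons, genes = genes)
  expect_equal(cand$id, c("c1", "c2"))
  expect_false(cand$pass_repeat[2])
  expect_true(cand$pass_all[1])
})
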