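test_that("generators are pure functions of the seed", {
  cfg <- sim_config(seed = 4, n_peaks = 500, genes_per_list = 20)
  g1 <- make_genome_and_genes(cfg)
  g2 <- make_genome_and_genes(cfg)
  expect_identical(g1, g2)

  p1 <- simulate_peaks(cfg, g1$genome, g1$lists, "oligodendrocyte")
  p2 <- simulate_peaks(cfg, g2$genome, g2$lists, "oligodendrocyte")
  expect_identical(as.data.frame(p1$peaks), as.data.frame(p2$peaks))

  s1 <- simulate_sequences(cfg)
  s2 <- simulate_sequences(cfg)
  expect_identical(s1, s2)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$sequences, f1); write_fasta(s2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  other <- make_genome_and_genes(sim_config(seed = 5, n_peaks = 500,
                                            genes_per_list = 20))
  expect_false(identical(g1$lists, other$lists))
})

test_that("gene generation respects counts, spacing and strand invariants", {
  cfg <- sim_config(seed = 2)
  gg <- make_genome_and_genes(cfg)
  all_genes <- do.call(rbind, lapply(gg$lists, as.data.frame))
  expect_equal(nrow(all_genes), 300)
  expect_equal(anyDuplicated(paste(all_genes$chrom, all_genes$tss)), 0)
  expect_equal(anyDuplicated(unlist(lapply(gg$lists, `[[`, "gene_id"))), 0)

  min_spacing <- 2 * cfg$window / 10
  for (ch in unique(all_genes$chrom)) {
    tss <- sort(all_genes$tss[all_genes$chrom == ch])
    if (length(tss) > 1) expect_gte(min(diff(tss)), min_spacing)
  }
  # bodies stay on the chromosome and respect TSS/strand conventions
  expect_true(all(all_genes$tx_start >= 0))
  expect_true(all(all_genes$tx_end <= cfg$chrom_length))
  with_plus <- all_genes[all_genes$strand == "+", ]
  with_minus <- all_genes[all_genes$strand == "-", ]
  expect_true(all(with_plus$tss == with_plus$tx_start))
  expect_true(all(with_minus$tss == with_minus$tx_end - 1))

  expect_error(make_genome_and_genes(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 1e6,
               genes_per_list = 200)), "too small")
})

test_that("simulated files round-trip through the readers", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(seed = 6, n_peaks = 300,
                                    genes_per_list = 15, n_sequences = 10),
                         dir)
  peaks <- read_bed(ds$paths$treatment)
  expect_equal(nrow(peaks), 300)
  expect_equal(as.data.frame(peaks)[c("chrom", "start", "end", "name")],
               as.data.frame(ds$peaks)[c("chrom", "start", "end", "name")])
  lists <- read_gene_table(ds$paths$genes)
  expect_named(lists, c("neuron", "astrocyte", "oligodendrocyte"))
  expect_identical(as.data.frame(lists$neuron),
                   as.data.frame(ds$lists$neuron))
  seqs <- read_fasta(ds$paths$fasta)
  expect_identical(seqs, ds$sequences)
})

test_that("null peaks are uniform and planted folds track the truth", {
  cfg0 <- sim_config(seed = 10, enrichment_fold = 1)
  gg <- make_genome_and_genes(cfg0)
  sim0 <- simulate_peaks(cfg0, gg$genome, gg$lists, "oligodendrocyte")
  expect_equal(sim0$truth$n_targeted, 0)
  counts <- unlist(sim0$truth$realized_distinct_counts)
  expected <- cfg0$n_peaks * 2 * cfg0$window / gg$genome$total_size *
    cfg0$genes_per_list
  expect_true(all(abs(counts - expected) < 5 * sqrt(expected)))

  cfg3 <- sim_config(seed = 10, enrichment_fold = 3)
  sim3 <- simulate_peaks(cfg3, gg$genome, gg$lists, "oligodendrocyte")
  expect_equal(sim3$truth$n_targeted,
               round(2 * cfg3$n_peaks * sim3$truth$target_span /
                       (gg$genome$total_size + 2 * sim3$truth$target_span)))
  tgt <- sim3$truth$realized_distinct_counts$oligodendrocyte
  bg <- mean(c(sim3$truth$realized_distinct_counts$neuron,
               sim3$truth$realized_distinct_counts$astrocyte))
  expect_gt(tgt / bg, 2)

  expect_equal(nrow(simulate_peaks(sim_config(seed = 1, n_peaks = 0),
                                   gg$genome, gg$lists)$peaks), 0)
  expect_error(simulate_peaks(sim_config(seed = 1), gg$genome, gg$lists,
                              "nonexistent"), "target_label")
})

test_that("control construction yields the exact filter arithmetic", {
  cfg <- sim_preset("filter-demo", seed = 3)
  gg <- make_genome_and_genes(cfg)
  sim <- simulate_peaks(cfg, gg$genome, gg$lists)
  expect_equal(nrow(sim$peaks), 2102)
  ctrl <- simulate_control(cfg, sim$peaks)
  expect_equal(nrow(ctrl), 17 + 5)
  res <- filter_against_control(sim$peaks, ctrl)
  expect_equal(nrow(res$removed), 17)
  expect_equal(nrow(res$retained), 2085)

  # zero-overlap control removes nothing
  cfg0 <- sim_config(seed = 3, n_peaks = 200, control_overlap_count = 0,
                     n_decoys = 8)
  sim0 <- simulate_peaks(cfg0, gg$genome, gg$lists)
  ctrl0 <- simulate_control(cfg0, sim0$peaks)
  expect_equal(nrow(filter_against_control(sim0$peaks, ctrl0)$removed), 0)

  expect_error(simulate_control(
    sim_config(seed = 1, n_peaks = 10, control_overlap_count = 11),
    simulate_peaks(sim_config(seed = 1, n_peaks = 10), gg$genome,
                   gg$lists)$peaks),
    "exceeds")
})

test_that("sequence plants match the recorded truth", {
  cfg <- sim_config(seed = 14, n_sequences = 40)
  sim <- simulate_sequences(cfg)
  expect_equal(length(sim$sequences), 40)
  expect_true(all(nchar(sim$sequences) == cfg$seq_length))
  planted <- sim$truth[sim$truth$planted, ]
  for (i in seq_len(nrow(planted))) {
    hits <- scan_motif(sim$sequences[[planted$seq_id[i]]], cfg$motif)
    expect_true(planted$offset[i] %in% hits$offset)
  }
})

test_that("unplanted sequences carry only chance-level hits", {
  cfg <- sim_config(seed = 15, n_sequences = 200, plant_rate = 0)
  seqs <- simulate_sequences(cfg)$sequences
  n_hits <- sum(vapply(seqs, function(s) nrow(scan_motif(s, cfg$motif)), 0L))
  m <- nchar(cfg$motif)
  L <- cfg$seq_length
  # 2 expansions x 2 strands x (L - m + 1) placements / 4^m per sequence
  expected <- length(seqs) * 2 * 2 * (L - m + 1) / 4^m
  expect_lt(abs(n_hits - expected), 6 * sqrt(expected))
})

test_that("planted spaced pairs are recoverable", {
  base <- simulate_sequences(sim_config(seed = 16, plant_rate = 0,
                                        n_sequences = 50))$sequences
  planted <- plant_spaced_pairs(base, "CTGGYAC", gap = 3, rate = 1, seed = 17)
  sp <- spaced_pair(planted$sequences, "CTGGYAC", "CTGGYAC", max_gap = 10)
  expect_equal(sp$best_gap, 3)
  expect_gte(sp$best_count, 45)
  expect_lt(sp$p_value, 1e-3)
})
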