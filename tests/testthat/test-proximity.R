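test_that("filter_against_control partitions the treatment set", {
  tr <- peak_set(data.frame(chrom = "chr1", start = c(0, 200, 400),
                            end = c(100, 300, 500)))
  ctrl <- peak_set(data.frame(chrom = "chr1", start = 250, end = 260))
  res <- filter_against_control(tr, ctrl)
  expect_equal(nrow(res$retained), 2)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$start, 200)
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(tr))

  none <- peak_set(data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0)))
  expect_equal(nrow(filter_against_control(tr, none)$retained), 3)

  g1 <- genome_model(c(chr1 = 1e6)); g2 <- genome_model(c(chr1 = 2e6))
  expect_error(filter_against_control(
    peak_set(tr, genome = g1), peak_set(as.data.frame(ctrl), genome = g2)),
    "different genomes")
})

test_that("dedup_unique_tss keeps the first record per (chrom, tss, strand)", {
  df <- rbind(make_gene(id = "iso1", tss = 100, len = 50),
              make_gene(id = "iso2", tss = 100, len = 80),
              make_gene(id = "g2", tss = 5000, len = 50))
  gl <- gene_list(df)
  dd <- dedup_unique_tss(gl)
  expect_equal(dd$gene_id, c("iso1", "g2"))

  df2 <- rbind(make_gene(id = "a", tss = 100), make_gene(id = "b", tss = 200))
  expect_equal(nrow(dedup_unique_tss(gene_list(df2))), 2)
  # strand distinguishes: same coordinate, opposite strands both kept
  df3 <- rbind(make_gene(id = "p", tss = 300, strand = "+"),
               make_gene(id = "m", tss = 300, strand = "-"))
  expect_equal(nrow(dedup_unique_tss(gene_list(df3))), 2)
})

test_that("peaks_per_gene counts midpoints in closed windows", {
  gl <- gene_list(make_gene(tss = 1e6, len = 5000))
  pk <- peak_set(data.frame(chrom = "chr1",
                            start = c(949900, 1049900), end = c(950100, 1050100)))
  res <- peaks_per_gene(pk, gl, window = 1e5)
  expect_equal(res$per_gene$n_peaks, 2)

  # midpoint exactly window bp away is counted (closed boundary)
  pk_edge <- peak_set(data.frame(chrom = "chr1", start = 1099950,
                                 end = 1100050))  # midpoint 1,100,000
  expect_equal(peaks_per_gene(pk_edge, gl, window = 1e5)$per_gene$n_peaks, 1)
  expect_equal(peaks_per_gene(
    peak_set(data.frame(chrom = "chr1", start = 1100051, end = 1100151)),
    gl, window = 1e5)$per_gene$n_peaks, 0)

  # a peak between two genes counts for both but once in the distinct total
  two <- gene_list(rbind(make_gene(id = "a", tss = 1e6),
                         make_gene(id = "b", tss = 1e6 + 5e4)))
  mid <- peak_set(data.frame(chrom = "chr1", start = 1024950, end = 1025050))
  res2 <- peaks_per_gene(mid, two, window = 1e5)
  expect_equal(res2$per_gene$n_peaks, c(1, 1))
  expect_equal(res2$assignments, 2)
  expect_equal(res2$distinct_peaks, 1)
})

test_that("peaks_per_gene tallies genes with 1, 2 and >=3 peaks", {
  gl <- gene_list(rbind(make_gene(id = "a", tss = 1e6),
                        make_gene(id = "b", tss = 5e6),
                        make_gene(id = "c", tss = 9e6)))
  mk <- function(mids) peak_set(data.frame(chrom = "chr1", start = mids - 50,
                                           end = mids + 50))
  pk <- mk(c(1e6, 5e6, 5e6 + 1000, 9e6, 9e6 + 1000, 9e6 + 2000, 2e7))
  res <- peaks_per_gene(pk, gl)
  expect_equal(unname(res$tally), c(1, 1, 1))
  expect_equal(res$distinct_peaks, 6)
})

test_that("categorize_peak follows the category taxonomy", {
  gp <- make_gene(strand = "+", tss = 10000, len = 5000)  # tx [10000,15000)
  expect_equal(categorize_peak(list(chrom = "chr1", start = 9200, end = 9800), gp),
               "UPSTREAM_0_1K")  # midpoint 9500, d = -500
  expect_equal(categorize_peak(list(chrom = "chr1", start = 11900, end = 12100), gp),
               "GENE_BODY")
  gm <- make_gene(strand = "-", tss = 14999, len = 5000)  # tx [10000,15000)
  expect_equal(categorize_peak(list(chrom = "chr1", start = 7900, end = 8100), gm),
               "DOWNSTREAM_WITHIN_100K")  # d = +6999, past 3' end

  # boundary and precedence cases
  expect_equal(categorize_peak(list(chrom = "chr1", start = 8950, end = 9050), gp),
               "UPSTREAM_0_1K")   # d = -1000 inclusive
  expect_equal(categorize_peak(list(chrom = "chr1", start = 8900, end = 9098), gp),
               "UPSTREAM_1_20K")  # d = -1001
  expect_equal(categorize_peak(list(chrom = "chr1", start = 10300, end = 10500), gp),
               "GENE_BODY")       # inside the gene though < 1 kb from the TSS
  expect_equal(categorize_peak(list(chrom = "chr1", start = 200000, end = 200100), gp),
               "NONE")
  expect_equal(categorize_peak(list(chrom = "chr2", start = 9200, end = 9800), gp),
               "NONE")
})

test_that("uniform background density and spacing", {
  rat <- genome_model(c(chr1 = 2.75e9))
  ub <- uniform_background(2085, rat)
  expect_equal(ub$mean_spacing, 2.75e9 / 2085)
  expect_equal(round(ub$mean_spacing / 1e6, 1), 1.3)

  expect_equal(uniform_background(1, rat)$mean_spacing, 2.75e9)
  small <- genome_model(c(chr1 = 1e6))
  expect_equal(uniform_background(10, small)$density, 1e-5)
  expect_error(uniform_background(0, rat), "n_peaks")
})

test_that("expected_count follows the naive uniform model", {
  rat <- genome_model(c(chr1 = 2.75e9))
  genes <- gene_list(do.call(rbind, lapply(1:200, function(i) {
    make_gene(id = paste0("g", i), tss = i * 1e6)
  })))
  expect_equal(expected_count(2085, rat, genes, window = 1e5),
               2085 / 2.75e9 * 4e7, tolerance = 1e-12)

  # span equal to the genome recovers all peaks (conservation)
  g <- genome_model(c(chr1 = 1e6))
  one <- gene_list(make_gene(tss = 5e5))
  expect_equal(expected_count(777, g, one, window = 5e5), 777)

  empty <- gene_list(make_gene())[0, ]
  expect_equal(expected_count(100, rat, gene_list(empty), 1e5), 0)
})

test_that("merged expected span removes double-counted window overlap", {
  g <- genome_model(c(chr1 = 1e7))
  near <- gene_list(rbind(make_gene(id = "a", tss = 1e6),
                          make_gene(id = "b", tss = 1e6 + 5e4)))
  naive <- expected_count(1000, g, near, window = 1e5)
  merged <- expected_count(1000, g, near, window = 1e5, merge_windows = TRUE)
  expect_equal(naive, 1000 / 1e7 * 4e5)
  expect_equal(merged, 1000 / 1e7 * (2e5 + 5e4 + 1))  # union of the windows
})

test_that("enrichment_test reproduces closed-form chi-squared values", {
  res <- enrichment_test(c(10, 20), c(15, 15))
  expect_equal(res$joint$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(res$joint$df, 1)
  expect_equal(res$joint$p_value, pchisq(10 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$per_list$fold, c(2 / 3, 4 / 3), tolerance = 1e-12)

  flat <- enrichment_test(c(30, 30, 30), c(30, 30, 30))
  expect_equal(flat$joint$statistic, 0)
  expect_equal(flat$joint$p_value, 1)

  near <- enrichment_test(c(39, 40), c(30.3, 30.3))
  expect_equal(near$per_list$fold, c(39, 40) / 30.3, tolerance = 1e-12)
  expect_true(all(near$per_list$fold < 1.4))

  expect_error(enrichment_test(c(1, 2), c(0, 3)), "expected")
})

test_that("TSS histogram bins signed distances strand-aware", {
  gl <- gene_list(make_gene(tss = 1e6, len = 5000))
  pk <- peak_set(data.frame(chrom = "chr1",
                            start = c(996900, 1001900),
                            end = c(997100, 1002100)))  # d = -3000, +2000
  h <- tss_histogram(pk, gl)
  expect_equal(h$bin_edges, seq(-1e5, 1e5, 5000))
  expect_equal(sum(h$counts), 2)
  expect_equal(h$counts[20], 1)  # [-5000, 0)
  expect_equal(h$counts[21], 1)  # [0, 5000]
  expect_equal(sum(h$counts), h$n_genes * 0 + 2)

  none <- tss_histogram(peak_set(data.frame(chrom = "chr1", start = 5e6,
                                            end = 5e6 + 100)), gl)
  expect_true(all(none$counts == 0))
  expect_error(tss_histogram(pk, gl, bin_width = 3001), "divide")
})

test_that("mirrored peaks around a minus-strand TSS reproduce the histogram", {
  tss <- 1e6
  offs <- c(-70000, -3000, 2000, 400, 99999)
  plus <- gene_list(make_gene(strand = "+", tss = tss))
  minus <- gene_list(make_gene(strand = "-", tss = tss))
  pk_plus <- peak_set(data.frame(chrom = "chr1", start = tss + offs - 50,
                                 end = tss + offs + 50))
  pk_minus <- peak_set(data.frame(chrom = "chr1", start = tss - offs - 50,
                                  end = tss - offs + 50))
  h1 <- tss_histogram(pk_plus, plus)
  h2 <- tss_histogram(pk_minus, minus)
  expect_identical(h1$counts, h2$counts)
})

test_that("histogram counts survive chromosome renaming and translation", {
  cfg <- sim_config(seed = 8, n_peaks = 300, genes_per_list = 20)
  gg <- make_genome_and_genes(cfg)
  pk <- simulate_peaks(cfg, gg$genome, gg$lists, "oligodendrocyte")$peaks
  gl <- gg$lists$oligodendrocyte
  h0 <- tss_histogram(pk, gl)

  ren <- function(x) paste0("scaffold_", x)
  pk2 <- peak_set(within(as.data.frame(pk), chrom <- ren(chrom)))
  gl2 <- gene_list(within(as.data.frame(gl), chrom <- ren(chrom)),
                   label = attr(gl, "label"))
  expect_identical(tss_histogram(pk2, gl2)$counts, h0$counts)

  shift <- 123456
  pk3 <- peak_set(within(as.data.frame(pk), {
    start <- start + shift; end <- end + shift
  }))
  gl3 <- gene_list(within(as.data.frame(gl), {
    tss <- tss + shift; tx_start <- tx_start + shift; tx_end <- tx_end + shift
  }), label = attr(gl, "label"))
  expect_identical(tss_histogram(pk3, gl3)$counts, h0$counts)
})

test_that("overlap_summary reports fractions and triple overlap", {
  a <- peak_set(data.frame(chrom = "chr1", start = c(0, 20, 40),
                           end = c(10, 30, 50)))
  b <- peak_set(data.frame(chrom = "chr1", start = c(5, 41), end = c(8, 60)))
  ov <- overlap_summary(a, b)
  expect_equal(ov$fraction_a_in_b, 2 / 3)

  self <- overlap_summary(a, a)
  expect_equal(self$fraction_a_in_b, 1)

  empty <- peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0)))
  tri <- overlap_summary(a, b, empty)
  expect_equal(tri$triple, 0)

  c_set <- peak_set(data.frame(chrom = "chr1", start = c(6, 25), end = c(9, 28)))
  tri2 <- overlap_summary(a, b, c_set)
  expect_equal(tri2$triple, 1)  # only [0,10) is hit by both b and c
  expect_lte(tri2$triple, min(tri2$a_in_b, tri2$a_in_c))
})

test_that("annotate_peaks emits one row per in-range pair", {
  lists <- list(gene_list(make_gene(tss = 1e6), label = "oligodendrocyte"))
  pk <- peak_set(data.frame(chrom = "chr1",
                            start = c(999400, 1002000, 5e6),
                            end = c(999600, 1002400, 5e6 + 200)))
  ann <- annotate_peaks(pk, lists)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$category, c("UPSTREAM_0_1K", "GENE_BODY"))
  expect_equal(sort(ann$distance), c(-500, 2200))
})
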