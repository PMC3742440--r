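#' Remove treatment peaks that have a corresponding control peak
#'
#' A treatment peak "corresponds" to a control peak when they share at
#' least 1 bp. The two returned sets partition the input exactly.
#'
#' @param treatment,control [peak_set()] objects on the same genome.
#' @return List with `retained` and `removed` [peak_set()]s.
#' @export
filter_against_control <- function(treatment, control) {
  gt <- attr(treatment, "genome"); gc <- attr(control, "genome")
  if (!is.null(gt) && !is.null(gc) && !identical(gt$chrom_sizes, gc$chrom_sizes)) {
    stop("treatment and control peak sets are on different genomes")
  }
  flags <- count_overlapping(treatment, control)$flags
  lab <- attr(treatment, "label")
  list(
    retained = peak_set(as.data.frame(treatment)[!flags, , drop = FALSE],
                        label = paste0(lab, "_specific"), genome = gt,
                        n_cols = attr(treatment, "n_cols")),
    removed = peak_set(as.data.frame(treatment)[flags, , drop = FALSE],
                       label = paste0(lab, "_in_control"), genome = gt,
                       n_cols = attr(treatment, "n_cols"))
  )
}

#' Keep one representative per unique TSS
#'
#' Records sharing an identical (chrom, tss, strand) collapse to the first
#' in input order, so genes with many isoforms are not over-represented in
#' window counts. Output order is stable.
#'
#' @param genes A [gene_list()].
#' @return A [gene_list()] with duplicates removed.
#' @export
dedup_unique_tss <- function(genes) {
  key <- paste(genes$chrom, genes$tss, genes$strand, sep = "\r")
  gene_list(as.data.frame(genes)[!duplicated(key), , drop = FALSE],
            label = attr(genes, "label"))
}

gene_windows_granges <- function(genes, window) {
  # window of midpoint positions m with |m - tss| <= window (0-based),
  # i.e. 1-based [tss - window + 1, tss + window + 1]; boundary closed
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss - window + 1,
                              end = genes$tss + window + 1)
  )
}

peak_points_granges <- function(peaks, peak_point = "midpoint") {
  if (peak_point == "midpoint") {
    m <- interval_midpoint(peaks$start, peaks$end)
    GenomicRanges::GRanges(seqnames = peaks$chrom,
                           ranges = IRanges::IRanges(start = m + 1, width = 1))
  } else {
    peaks_to_granges(peaks)
  }
}

#' Count peaks within a window of each gene's TSS
#'
#' A peak is assigned to a gene when its reference point (midpoint by
#' default) lies within `window` bp of the gene's TSS on either side
#' (closed boundary). One peak may count toward several genes; the
#' list-level total counts each peak once.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_list()].
#' @param window Half-width of the TSS window in bp (default 100 kb).
#' @param peak_point `"midpoint"` (default) or `"any"` (any-overlap mode).
#' @return List with `per_gene` (data frame `gene_id`, `n_peaks`), `tally`
#'   (genes with exactly 1, exactly 2, or >= 3 peaks), `distinct_peaks`
#'   (peaks falling in any window of the list, counted once) and
#'   `assignments` (total peak-gene pairs).
#' @export
peaks_per_gene <- function(peaks, genes, window = 1e5,
                           peak_point = c("midpoint", "any")) {
  peak_point <- match.arg(peak_point)
  stopifnot(window > 0)
  n_genes <- nrow(genes)
  counts <- integer(n_genes)
  distinct <- 0L
  assignments <- 0L
  if (nrow(peaks) && n_genes) {
    hits <- GenomicRanges::findOverlaps(
      peak_points_granges(peaks, peak_point),
      gene_windows_granges(genes, window),
      ignore.strand = TRUE
    )
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = n_genes)
    counts <- as.integer(tab)
    distinct <- length(unique(S4Vectors::queryHits(hits)))
    assignments <- length(hits)
  }
  list(
    per_gene = data.frame(gene_id = genes$gene_id, n_peaks = counts,
                          stringsAsFactors = FALSE),
    tally = c(`1` = sum(counts == 1), `2` = sum(counts == 2),
              `>=3` = sum(counts >= 3)),
    distinct_peaks = distinct,
    assignments = assignments
  )
}

categorize_midpoints <- function(m, gene, window = 1e5) {
  d <- signed_tss_distance(m, gene)
  in_body <- m >= gene$tx_start & m < gene$tx_end
  past3 <- if (gene$strand == "+") m >= gene$tx_end else m < gene$tx_start
  out <- rep("NONE", length(m))
  out[d > 0 & past3 & d <= window] <- "DOWNSTREAM_WITHIN_100K"
  out[d < 0 & -d > 20000 & -d <= 1e5] <- "UPSTREAM_20_100K"
  out[d < 0 & -d > 1000 & -d <= 20000] <- "UPSTREAM_1_20K"
  out[d < 0 & -d <= 1000] <- "UPSTREAM_0_1K"
  out[in_body] <- "GENE_BODY"
  out
}

#' Proximity category of a peak relative to a gene
#'
#' Taxonomy used for the binding-site pie charts: the peak midpoint is
#' classified as inside the gene body (which takes precedence), within
#' 1 kb / 1--20 kb / 20--100 kb upstream of the TSS, or downstream of the
#' 3' end but still within `window` of the TSS; anything else is `NONE`.
#' The upstream bin edges are fixed by the taxonomy; `window` caps only the
#' downstream category.
#'
#' @param peak One-row [peak_set()] slice or list with `start`, `end`.
#' @param gene A single gene record.
#' @param window Downstream cap in bp.
#' @return One of `"GENE_BODY"`, `"UPSTREAM_0_1K"`, `"UPSTREAM_1_20K"`,
#'   `"UPSTREAM_20_100K"`, `"DOWNSTREAM_WITHIN_100K"`, `"NONE"`.
#' @export
categorize_peak <- function(peak, gene, window = 1e5) {
  m <- interval_midpoint(peak$start, peak$end)
  if (!is.null(peak$chrom) && as.character(peak$chrom) != gene$chrom) return("NONE")
  categorize_midpoints(m, gene, window)
}

#' Annotate all peak-gene pairs within range
#'
#' @param peaks A [peak_set()].
#' @param lists A list of [gene_list()] objects.
#' @param window TSS window half-width in bp.
#' @return Data frame with `list_label`, `gene_id`, `peak_name`,
#'   `distance` (signed, strand-aware) and `category`, one row per
#'   peak-gene pair whose category is not `NONE`.
#' @export
annotate_peaks <- function(peaks, lists, window = 1e5) {
  if (inherits(lists, "gene_list")) lists <- list(lists)
  m <- interval_midpoint(peaks$start, peaks$end)
  rows <- list()
  for (gl in lists) {
    lb <- attr(gl, "label")
    for (i in seq_len(nrow(gl))) {
      gene <- gl[i, ]
      on_chr <- which(peaks$chrom == gene$chrom)
      if (!length(on_chr)) next
      cat_i <- categorize_midpoints(m[on_chr], gene, window)
      keep <- cat_i != "NONE"
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        list_label = lb, gene_id = gene$gene_id,
        peak_name = peaks$name[on_chr][keep],
        distance = signed_tss_distance(m[on_chr][keep], gene),
        category = cat_i[keep], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(list_label = character(0), gene_id = character(0),
                      peak_name = character(0), distance = numeric(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Uniform background peak density
#'
#' Under the uniform model, density = peaks / genome size and peaks are
#' expected every `total_size / n_peaks` bp on average.
#'
#' @param n_peaks Number of peaks (> 0).
#' @param genome A [genome_model()].
#' @return List with `density` (peaks per bp) and `mean_spacing` (bp).
#' @export
uniform_background <- function(n_peaks, genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_peaks <= 0) stop("n_peaks must be > 0")
  if (genome$total_size <= 0) stop("genome is empty")
  list(density = n_peaks / genome$total_size,
       mean_spacing = genome$total_size / n_peaks)
}

#' Expected peak count in TSS windows under the uniform model
#'
#' Default span is the naive `2 * window` bp per unique-TSS gene, without
#' merging overlapping windows (the back-of-envelope expectation used for
#' the printed comparison). `merge_windows = TRUE` instead measures the
#' merged union of windows, clipped to chromosome ends, which is the exact
#' span the midpoint-in-window counting can see.
#'
#' @param n_peaks Total peaks on the genome.
#' @param genome A [genome_model()].
#' @param genes A [gene_list()].
#' @param window TSS window half-width in bp.
#' @param merge_windows Merge overlapping windows and clip to chromosomes?
#' @param dedup Collapse records sharing a TSS first (default TRUE)?
#' @return Expected number of peaks (real).
#' @export
expected_count <- function(n_peaks, genome, genes, window = 1e5,
                           merge_windows = FALSE, dedup = TRUE) {
  stopifnot(inherits(genome, "genome_model"))
  if (nrow(genes) == 0) return(0)
  if (dedup) genes <- dedup_unique_tss(genes)
  density <- n_peaks / genome$total_size
  if (!merge_windows) {
    span <- nrow(genes) * 2 * window
  } else {
    lo <- pmax(genes$tss - window, 0)
    hi <- pmin(genes$tss + window, genome$chrom_sizes[genes$chrom] - 1)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = lo + 1, end = hi + 1)
    ))
    span <- sum(as.numeric(IRanges::width(gr)))
  }
  density * span
}

#' Fold enrichment and chi-squared tests of observed vs expected counts
#'
#' Per list, fold = observed / expected and a one-sample chi-squared
#' statistic `(obs - exp)^2 / exp` (df = 1, upper tail) are reported. The
#' joint test across lists is, by default, conditional on the observed
#' total: expectations are rescaled to sum to the observed total and the
#' statistic is referred to chi-squared with `k - 1` df (the classic
#' multinomial goodness-of-fit, which is calibrated when only the
#' *distribution* of peaks across lists is at issue). With
#' `conditional = FALSE` the raw expectations are used with `k` df.
#'
#' @param observed Named numeric vector of observed counts per gene list.
#' @param expected Numeric vector of uniform-model expected counts (> 0).
#' @param conditional Condition the joint test on the observed total?
#' @return An `enrichment_report`: list with `per_list` (data frame
#'   `list`, `observed`, `expected`, `fold`, `chi2`, `p_value`) and
#'   `joint` (`statistic`, `df`, `p_value`, `conditional`).
#' @export
enrichment_test <- function(observed, expected, conditional = TRUE) {
  k <- length(observed)
  stopifnot(length(expected) == k)
  if (any(expected <= 0)) stop("all expected counts must be > 0")
  fold <- observed / expected
  chi2_i <- (observed - expected)^2 / expected
  p_i <- stats::pchisq(chi2_i, df = 1, lower.tail = FALSE)
  if (conditional && k >= 2) {
    e <- expected * sum(observed) / sum(expected)
    stat <- sum((observed - e)^2 / e)
    df <- k - 1L
  } else {
    stat <- sum(chi2_i)
    df <- k
  }
  structure(list(
    per_list = data.frame(
      list = if (is.null(names(observed))) as.character(seq_len(k)) else names(observed),
      observed = as.numeric(observed), expected = as.numeric(expected),
      fold = as.numeric(fold), chi2 = as.numeric(chi2_i),
      p_value = as.numeric(p_i), stringsAsFactors = FALSE
    ),
    joint = list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = max(df, 1L), lower.tail = FALSE),
                 conditional = conditional && k >= 2)
  ), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>\n")
  print.data.frame(x$per_list, digits = 4)
  cat(sprintf("joint chi2 = %.4g, df = %d, p = %.4g%s\n",
              x$joint$statistic, x$joint$df, x$joint$p_value,
              if (x$joint$conditional) " (conditional on total)" else ""))
  invisible(x)
}

#' Histogram of peak incidence relative to TSSs
#'
#' For every (peak, gene) pair with the peak midpoint within `range` bp of
#' the TSS, the strand-aware signed distance is binned (upstream negative).
#' A distance exactly on a bin edge goes to the bin closer to the TSS;
#' distance 0 goes to the first downstream bin.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_list()].
#' @param range Histogram half-range in bp (default 100 kb).
#' @param bin_width Bin width in bp; must divide `2 * range`.
#' @param normalization `"counts"` or `"per_gene"` (counts divided by the
#'   number of genes).
#' @return A `tss_histogram`: list with `bin_edges`, `counts`, `values`
#'   (normalized when requested), `n_genes`, `normalization`.
#' @export
tss_histogram <- function(peaks, genes, range = 1e5, bin_width = 5000,
                          normalization = c("counts", "per_gene")) {
  normalization <- match.arg(normalization)
  if ((2 * range) %% bin_width != 0) stop("bin_width must divide 2 * range")
  nbins <- as.integer(2 * range / bin_width)
  half <- nbins %/% 2L
  counts <- integer(nbins)
  m <- interval_midpoint(peaks$start, peaks$end)
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    d <- signed_tss_distance(m[peaks$chrom == gene$chrom], gene)
    d <- d[abs(d) <= range]
    if (!length(d)) next
    idx <- ifelse(d < 0,
                  floor((d + range) / bin_width) + 1,
                  half + pmax(1, ceiling(d / bin_width)))
    counts <- counts + tabulate(idx, nbins = nbins)
  }
  structure(list(
    bin_edges = seq(-range, range, by = bin_width),
    counts = counts,
    values = if (normalization == "per_gene") counts / nrow(genes) else counts,
    n_genes = nrow(genes),
    normalization = normalization
  ), class = "tss_histogram")
}

#' Overlap summary between two or three peak sets
#'
#' Reports the fraction of set-A peaks overlapped (>= 1 bp) by set B (and
#' by set C), plus the triple-overlap count: A peaks overlapped by at
#' least one B peak *and* at least one C peak.
#'
#' @param a,b [peak_set()] objects; `c` optional.
#' @param c Optional third [peak_set()].
#' @return An `overlap_summary`: list with set sizes, pairwise flagged
#'   counts and fractions, and `triple` when `c` is given.
#' @export
overlap_summary <- function(a, b, c = NULL) {
  ab <- count_overlapping(a, b)
  ba <- count_overlapping(b, a)
  out <- list(
    n_a = nrow(a), n_b = nrow(b),
    a_in_b = ab$count, fraction_a_in_b = if (nrow(a)) ab$count / nrow(a) else NA_real_,
    b_in_a = ba$count, fraction_b_in_a = if (nrow(b)) ba$count / nrow(b) else NA_real_
  )
  if (!is.null(c)) {
    ac <- count_overlapping(a, c)
    out$n_c <- nrow(c)
    out$a_in_c <- ac$count
    out$fraction_a_in_c <- if (nrow(a)) ac$count / nrow(a) else NA_real_
    out$triple <- sum(ab$flags & ac$flags)
  }
  structure(out, class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> |A|=%d |B|=%d; A overlapped by B: %d (%.1f%%)\n",
              x$n_a, x$n_b, x$a_in_b, 100 * x$fraction_a_in_b))
  if (!is.null(x$triple)) {
    cat(sprintf("  A overlapped by C: %d (%.1f%%); triple overlap: %d\n",
                x$a_in_c, 100 * x$fraction_a_in_c, x$triple))
  }
  invisible(x)
}
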