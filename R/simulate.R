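#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the study design the pipeline targets: three disjoint cell-type gene
#' lists of 100 genes on a 250 Mb ten-chromosome genome, 2,000 peaks with a
#' 3-fold planted density enrichment within +/-100 kb of the target list's
#' TSSs, and 100 x 500 bp sequences carrying the CTGGYAC consensus planted
#' in 80% of sequences with a tight (sd 10 bp) central bias.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_chroms,chrom_length Genome shape.
#' @param n_lists,genes_per_list,list_labels Gene-list shape.
#' @param n_peaks Total treatment peaks.
#' @param peak_width Fixed width or `c(min, max)` range in bp.
#' @param enrichment_fold Planted within-window density fold (>= 1) for the
#'   target list.
#' @param window TSS window half-width in bp.
#' @param n_sequences,seq_length Sequence-set shape.
#' @param motif IUPAC consensus planted in sequences.
#' @param plant_rate Fraction of sequences receiving one motif instance.
#' @param central_sd Standard deviation (bp) of the planted position around
#'   the sequence center.
#' @param control_overlap_count Control peaks constructed to overlap a
#'   distinct treatment peak each.
#' @param n_decoys Control peaks overlapping nothing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 10L, chrom_length = 25e6,
                       n_lists = 3L, genes_per_list = 100L,
                       list_labels = c("neuron", "astrocyte", "oligodendrocyte"),
                       n_peaks = 2000L, peak_width = c(200L, 800L),
                       enrichment_fold = 3, window = 1e5,
                       n_sequences = 100L, seq_length = 500L,
                       motif = "CTGGYAC", plant_rate = 0.8, central_sd = 10,
                       control_overlap_count = 17L, n_decoys = 0L) {
  stopifnot(enrichment_fold >= 1, plant_rate >= 0, plant_rate <= 1,
            n_chroms >= 1, chrom_length > 0, n_lists >= 1,
            genes_per_list >= 1, window > 0, seq_length > nchar(motif),
            seed == floor(seed), abs(seed) < 2^31)
  if (length(list_labels) < n_lists) {
    list_labels <- c(list_labels, paste0("list", seq_len(n_lists)))
  }
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_lists = as.integer(n_lists),
    genes_per_list = as.integer(genes_per_list),
    list_labels = list_labels[seq_len(n_lists)],
    n_peaks = as.integer(n_peaks), peak_width = peak_width,
    enrichment_fold = enrichment_fold, window = window,
    n_sequences = as.integer(n_sequences), seq_length = as.integer(seq_length),
    motif = check_motif(motif), plant_rate = plant_rate,
    central_sd = central_sd,
    control_overlap_count = as.integer(control_overlap_count),
    n_decoys = as.integer(n_decoys)
  ), class = "sim_config")
}

#' Preset simulation configurations
#'
#' * `tss-null`: uniform peaks (fold 1) -- the null for type-I checks.
#' * `tss-enriched`: 3-fold planted enrichment near the target list.
#' * `motif-demo`: sequence set with a planted, centrally biased consensus.
#' * `filter-demo`: 2,102 treatment peaks of which exactly 17 overlap a
#'   control peak, mirroring the treatment-vs-control filter arithmetic.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("tss-null", "tss-enriched", "motif-demo",
                                "filter-demo"),
                       seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "tss-null" = sim_config(seed = seed, enrichment_fold = 1),
    "tss-enriched" = sim_config(seed = seed, enrichment_fold = 3),
    "motif-demo" = sim_config(seed = seed),
    "filter-demo" = sim_config(seed = seed, n_peaks = 2102L,
                               enrichment_fold = 1,
                               control_overlap_count = 17L, n_decoys = 5L)
  )
}

# distinct sub-seeds per generator so each op is independently reproducible
sim_seed <- function(config, offset) (config$seed * 7L + offset) %% .Machine$integer.max

#' Generate a genome and disjoint cell-type gene lists
#'
#' TSSs are drawn uniformly per chromosome with a minimum inter-TSS spacing
#' of `2 * window / 10`; strands are random; gene bodies are 5--100 kb and
#' always fit on the chromosome. List membership is a random partition, so
#' the lists are disjoint and interleaved along the genome.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome_model()]) and `lists` (named list
#'   of [gene_list()]s).
#' @export
make_genome_and_genes <- function(config) {
  genome <- genome_model(setNames(rep(config$chrom_length, config$n_chroms),
                                  paste0("chr", seq_len(config$n_chroms))))
  n_genes <- config$n_lists * config$genes_per_list
  min_spacing <- 2 * config$window / 10
  margin <- 1e5  # largest gene body; keeps bodies on-chromosome
  withr::with_seed(sim_seed(config, 0L), {
    chrom <- sample(names(genome$chrom_sizes), n_genes, replace = TRUE,
                    prob = genome$chrom_sizes)
    tss <- numeric(n_genes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      n_c <- length(idx)
      span <- genome$chrom_sizes[[ch]] - 2 * margin - (n_c - 1) * min_spacing
      if (span <= 0) {
        stop("genome too small for ", n_genes, " genes with spacing ",
             min_spacing)
      }
      pos <- sort(runif(n_c, 0, span))
      tss[idx] <- floor(pos + margin + (seq_len(n_c) - 1) * min_spacing)
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    body_len <- floor(runif(n_genes, 5e3, 1e5))
    tx_start <- ifelse(strand == "+", tss, tss + 1 - body_len)
    tx_end <- ifelse(strand == "+", tss + body_len, tss + 1)
    membership <- sample(rep(config$list_labels, config$genes_per_list))
  })
  df <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand, tss = tss,
    tx_start = tx_start, tx_end = tx_end, stringsAsFactors = FALSE
  )
  lists <- lapply(config$list_labels, function(lb) {
    gene_list(df[membership == lb, , drop = FALSE], label = lb)
  })
  names(lists) <- config$list_labels
  list(genome = genome, lists = lists)
}

merged_tss_windows <- function(genes, window, genome) {
  lo <- pmax(genes$tss - window, 0)
  hi <- pmin(genes$tss + window, genome$chrom_sizes[genes$chrom] - 1)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = lo + 1, end = hi + 1)
  ))
}

draw_widths <- function(n, peak_width) {
  if (length(peak_width) == 1) rep(as.numeric(peak_width), n)
  else floor(runif(n, peak_width[1], peak_width[2] + 1))
}

midpoints_to_peaks <- function(chrom, mid, widths, genome, prefix) {
  start <- pmax(0, mid - floor(widths / 2))
  end <- start + widths
  len <- genome$chrom_sizes[chrom]
  shift <- pmax(0, end - len)
  start <- start - shift
  end <- end - shift
  n <- length(mid)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = sprintf("%s_%05d", prefix, seq_len(n)),
             score = round(runif(n, 10, 100), 2),
             strand = rep(".", n), extra = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Simulate a peak set with planted TSS-proximal enrichment
#'
#' Background peak midpoints are uniform over the genome. To plant a
#' density fold f for the target list, additional peak midpoints are drawn
#' uniformly over the merged union of +/-window intervals around the
#' target TSSs (span W_T, clipped to chromosome ends). Requiring
#' (n_bg/G + n_t/W_T) = f * (n_bg/G) with n_bg + n_t = n gives the
#' allocation n_t = (f - 1) n W_T / (G + (f - 1) W_T): the planted
#' within-window density is f times the surrounding background density.
#' Relative to the all-peaks uniform expectation the asymptotic measured
#' fold is therefore f G / (G + (f - 1) W_T), slightly below f.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_model()].
#' @param lists Named list of [gene_list()]s.
#' @param target_label Which list receives the enrichment; `NULL` (or
#'   fold 1) places all peaks uniformly.
#' @return List with `peaks` (a [peak_set()], sorted by position) and
#'   `truth` (planted parameters and realized per-list counts).
#' @export
simulate_peaks <- function(config, genome, lists, target_label = NULL) {
  f <- config$enrichment_fold
  if (f < 1) stop("enrichment_fold must be >= 1")
  n <- config$n_peaks
  G <- genome$total_size
  chroms <- names(genome$chrom_sizes)
  w_t <- 0
  n_targeted <- 0L
  if (!is.null(target_label) && f > 1) {
    if (!target_label %in% names(lists)) {
      stop("target_label must name one of the gene lists")
    }
    target_windows <- merged_tss_windows(lists[[target_label]], config$window,
                                         genome)
    w_t <- sum(as.numeric(IRanges::width(target_windows)))
    n_targeted <- round((f - 1) * n * w_t / (G + (f - 1) * w_t))
  }
  n_bg <- n - n_targeted
  withr::with_seed(sim_seed(config, 1L), {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE, prob = genome$chrom_sizes)
    bg_mid <- floor(runif(n_bg) * genome$chrom_sizes[bg_chrom])
    if (n_targeted > 0) {
      widths_w <- as.numeric(IRanges::width(target_windows))
      pick <- sample(length(target_windows), n_targeted, replace = TRUE,
                     prob = widths_w)
      within <- floor(runif(n_targeted) * widths_w[pick])
      tg_chrom <- as.character(GenomicRanges::seqnames(target_windows))[pick]
      tg_mid <- BiocGenerics::start(target_windows)[pick] - 1 + within
    } else {
      tg_chrom <- character(0)
      tg_mid <- numeric(0)
    }
    df <- midpoints_to_peaks(c(bg_chrom, tg_chrom), c(bg_mid, tg_mid),
                             draw_widths(n, config$peak_width), genome, "pk")
  })
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df$name <- sprintf("pk_%05d", seq_len(nrow(df)))
  peaks <- peak_set(df, label = "treatment", genome = genome)
  realized <- lapply(lists, function(gl) {
    peaks_per_gene(peaks, dedup_unique_tss(gl), window = config$window)$distinct_peaks
  })
  truth <- list(
    seed = config$seed, n_peaks = n, n_background = n_bg,
    n_targeted = n_targeted, target_label = target_label,
    planted_fold = f, target_span = w_t, genome_size = G,
    expected_fold_vs_uniform = if (w_t > 0) f * G / (G + (f - 1) * w_t) else 1,
    realized_distinct_counts = realized
  )
  list(peaks = peaks, truth = truth)
}

#' Simulate a control peak set for the treatment-vs-control filter
#'
#' Constructs exactly `control_overlap_count` control peaks, each a copy of
#' a distinct treatment peak chosen among peaks that overlap no other
#' treatment peak (so the downstream filter removes exactly that many),
#' plus `n_decoys` uniform peaks overlapping no treatment peak.
#'
#' @param config A [sim_config()].
#' @param peaks The treatment [peak_set()].
#' @return A [peak_set()] labelled `"control"`.
#' @export
simulate_control <- function(config, peaks) {
  k <- config$control_overlap_count
  if (k > nrow(peaks)) stop("control_overlap_count exceeds number of peaks")
  genome <- attr(peaks, "genome")
  gr <- peaks_to_granges(peaks)
  self_hits <- GenomicRanges::findOverlaps(gr, gr)
  touched <- S4Vectors::queryHits(self_hits)[
    S4Vectors::queryHits(self_hits) != S4Vectors::subjectHits(self_hits)]
  isolated <- setdiff(seq_len(nrow(peaks)), unique(touched))
  if (length(isolated) < k) {
    stop("cannot construct ", k, " non-interfering control overlaps; only ",
         length(isolated), " isolated treatment peaks")
  }
  withr::with_seed(sim_seed(config, 2L), {
    chosen <- sort(sample(isolated, k))
    df <- as.data.frame(peaks)[chosen, c("chrom", "start", "end"), drop = FALSE]
    if (config$n_decoys > 0) {
      chroms <- names(genome$chrom_sizes)
      decoys <- NULL
      tries <- 0L
      while (is.null(decoys) || nrow(decoys) < config$n_decoys) {
        tries <- tries + 1L
        if (tries > 100L) stop("could not place non-overlapping decoys")
        need <- config$n_decoys - if (is.null(decoys)) 0L else nrow(decoys)
        ch <- sample(chroms, need, replace = TRUE, prob = genome$chrom_sizes)
        mid <- floor(runif(need) * genome$chrom_sizes[ch])
        cand <- midpoints_to_peaks(ch, mid, draw_widths(need, config$peak_width),
                                   genome, "decoy")
        ok <- !count_overlapping(cand, peaks)$flags
        decoys <- rbind(decoys, cand[ok, c("chrom", "start", "end"),
                                     drop = FALSE])
      }
      df <- rbind(df, decoys[seq_len(config$n_decoys), , drop = FALSE])
    }
  })
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df$name <- sprintf("ctrl_%05d", seq_len(nrow(df)))
  peak_set(df, label = "control", genome = genome)
}

realize_motif <- function(motif) {
  letters <- strsplit(motif, "")[[1]]
  paste(vapply(Biostrings::IUPAC_CODE_MAP[letters], function(s) {
    opts <- strsplit(s, "")[[1]]
    opts[sample.int(length(opts), 1)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

random_dna <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate fixed-length sequences with a planted, centrally biased motif
#'
#' Backgrounds are i.i.d. uniform A/C/G/T. A fraction `plant_rate` of
#' sequences receives one motif instance (degenerate positions realized
#' uniformly, strand random) whose center is drawn from a normal centered
#' at L/2 with sd `central_sd`, clipped to valid offsets.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector) and `truth`
#'   (data frame of per-sequence plants: offset, strand, realized m-mer).
#' @export
simulate_sequences <- function(config) {
  n <- config$n_sequences
  L <- config$seq_length
  m <- nchar(config$motif)
  withr::with_seed(sim_seed(config, 3L), {
    seqs <- random_dna(n, L)
    planted <- runif(n) < config$plant_rate
    offset <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    realized <- rep(NA_character_, n)
    for (i in which(planted)) {
      inst <- realize_motif(config$motif)
      strand[i] <- sample(c("+", "-"), 1)
      ins <- if (strand[i] == "+") inst else revcomp(inst)
      center <- stats::rnorm(1, L / 2, config$central_sd)
      offset[i] <- max(0L, min(L - m, as.integer(round(center - m / 2))))
      substr(seqs[i], offset[i] + 1L, offset[i] + m) <- ins
      realized[i] <- inst
    }
  })
  names(seqs) <- sprintf("seq_%04d", seq_len(n))
  truth <- data.frame(seq_id = names(seqs), planted = planted,
                      offset = offset, strand = strand, realized = realized,
                      stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Plant a spaced motif pair into existing sequences
#'
#' Generator utility for the spaced-pair statistic: inserts, into a
#' fraction `rate` of the sequences, two independently realized instances
#' of `motif` separated by exactly `gap` random bases, at a uniform
#' position.
#'
#' @param sequences Named character vector.
#' @param motif IUPAC consensus.
#' @param gap Bases strictly between the two instances.
#' @param rate Fraction of sequences receiving a pair.
#' @param seed Integer seed.
#' @return List with `sequences` (modified) and `truth` (data frame of
#'   insert offsets).
#' @export
plant_spaced_pairs <- function(sequences, motif, gap = 3, rate = 1,
                               seed = 1L) {
  motif <- check_motif(motif)
  m <- nchar(motif)
  ins_len <- 2 * m + gap
  withr::with_seed(seed, {
    chosen <- which(runif(length(sequences)) < rate)
    offset <- rep(NA_integer_, length(sequences))
    for (i in chosen) {
      L <- nchar(sequences[i])
      if (L < ins_len) next
      spacer <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                      collapse = "")
      ins <- paste0(realize_motif(motif), spacer, realize_motif(motif))
      offset[i] <- sample.int(L - ins_len + 1L, 1) - 1L
      substr(sequences[i], offset[i] + 1L, offset[i] + ins_len) <- ins
    }
  })
  list(sequences = sequences,
       truth = data.frame(seq_id = names(sequences), offset = offset,
                          stringsAsFactors = FALSE))
}

#' Shuffle each sequence's letters
#'
#' Mononucleotide shuffle preserving per-sequence base composition; the
#' standard negative set for discriminative motif discovery.
#'
#' @param sequences Character vector.
#' @param seed Integer seed.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(sequences, seed = 1L) {
  withr::with_seed(seed, {
    out <- vapply(sequences, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "", USE.NAMES = FALSE)
  })
  names(out) <- names(sequences)
  out
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all generators for a configuration and writes `genome.tsv`,
#' `genes.tsv`, `treatment.bed`, `control.bed`, `sequences.fasta` and
#' `truth.json` into `dir`.
#'
#' @param config A [sim_config()] (see also [sim_preset()]).
#' @param dir Output directory (created if needed).
#' @param target_label List receiving the enrichment; defaults to the last
#'   list label.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, dir,
                             target_label = utils::tail(config$list_labels, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gg <- make_genome_and_genes(config)
  sim <- simulate_peaks(config, gg$genome, gg$lists, target_label = target_label)
  control <- simulate_control(config, sim$peaks)
  seqs <- simulate_sequences(config)
  paths <- list(
    genome = file.path(dir, "genome.tsv"),
    genes = file.path(dir, "genes.tsv"),
    treatment = file.path(dir, "treatment.bed"),
    control = file.path(dir, "control.bed"),
    fasta = file.path(dir, "sequences.fasta"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.table(
    data.frame(chrom = names(gg$genome$chrom_sizes),
               length = gg$genome$chrom_sizes),
    paths$genome, sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_table(gg$lists, paths$genes)
  write_bed(sim$peaks, paths$treatment)
  write_bed(control, paths$control)
  write_fasta(seqs$sequences, paths$fasta)
  truth <- c(sim$truth, list(
    motif = config$motif, plant_rate = config$plant_rate,
    central_sd = config$central_sd,
    control_overlap_count = config$control_overlap_count,
    sequence_plants = seqs$truth
  ))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(genome = gg$genome, lists = gg$lists, peaks = sim$peaks,
                 control = control, sequences = seqs$sequences,
                 truth = truth, paths = paths))
}
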