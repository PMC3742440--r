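default_params <- function() {
  list(window = 1e5, bin_width = 5000, central_width = 100, max_gap = 10,
       k_min = 6, k_max = 8, peak_point = "midpoint", merge_windows = FALSE,
       motif = NULL, seed = 1L)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys: input paths `genome`, `peaks`, `control`, `genes`,
#' `fasta`, `fasta_negatives`, `peaks_b`, `peaks_c`; `out_dir`; and a
#' `params` block (`window`, `bin_width`, `central_width`, `max_gap`,
#' `k_min`, `k_max`, `peak_point`, `merge_windows`, `motif`, `seed`).
#' Missing parameters take package defaults.
#'
#' @param path Path to a YAML file.
#' @return A run-configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$params <- utils::modifyList(default_params(), cfg$params %||% list())
  for (key in c("genome", "peaks", "control", "genes", "fasta",
                "fasta_negatives", "peaks_b", "peaks_c")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config input '", key, "' does not exist: ", cfg[[key]])
    }
  }
  cfg
}

read_genome_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_model(setNames(df$length, df$chrom))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: control filtering, per-gene peak annotation,
#' uniform-background enrichment testing, TSS-relative histograms, peak-set
#' overlap, and the motif stages (scan, central enrichment, spaced pair,
#' discovery). Stages whose inputs are absent from the configuration are
#' skipped and noted in the summary. Per-stage tables are written as TSV,
#' statistics as JSON, plus a `summary.json` with a parameter echo, input
#' checksums, package version and wall-clock time. Identical configuration
#' and inputs reproduce all non-timing fields.
#'
#' @param config A configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  out_dir <- config$out_dir %||% "chipprox_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  inputs <- Filter(Negate(is.null),
                   config[c("genome", "peaks", "control", "genes", "fasta",
                            "fasta_negatives", "peaks_b", "peaks_c")])
  summary <- list(
    package = "chipprox",
    version = as.character(utils::packageVersion("chipprox")),
    parameters = params,
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    stages = list()
  )
  note <- function(name, status, result = NULL) {
    summary$stages[[name]] <<- c(list(status = status), result)
  }

  genome <- if (!is.null(config$genome)) {
    stage("genome", read_genome_tsv(config$genome))
  }
  peaks <- if (!is.null(config$peaks)) {
    stage("read_peaks", read_bed(config$peaks, genome = genome))
  }

  if (!is.null(peaks) && !is.null(config$control)) {
    control <- stage("filter", read_bed(config$control, genome = genome))
    flt <- stage("filter", filter_against_control(peaks, control))
    write_bed(flt$retained, file.path(out_dir, "peaks_retained.bed"))
    write_bed(flt$removed, file.path(out_dir, "peaks_removed.bed"))
    note("filter", "run", list(n_input = nrow(peaks),
                               n_retained = nrow(flt$retained),
                               n_removed = nrow(flt$removed)))
    peaks <- flt$retained
  } else note("filter", "skipped")

  lists <- if (!is.null(config$genes)) {
    stage("read_genes", lapply(read_gene_table(config$genes), dedup_unique_tss))
  }

  if (!is.null(peaks) && !is.null(lists)) {
    per_list <- stage("annotate", lapply(lists, function(gl) {
      peaks_per_gene(peaks, gl, window = params$window,
                     peak_point = params$peak_point)
    }))
    counts_df <- do.call(rbind, lapply(names(per_list), function(lb) {
      df <- per_list[[lb]]$per_gene
      df$list_label <- lb
      df
    }))
    utils::write.table(counts_df, file.path(out_dir, "per_gene_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    anno <- stage("annotate", annotate_peaks(peaks, lists,
                                             window = params$window))
    utils::write.table(anno, file.path(out_dir, "peak_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("annotate", "run",
         list(distinct_peaks = lapply(per_list, `[[`, "distinct_peaks"),
              tallies = lapply(per_list, `[[`, "tally")))

    if (!is.null(genome)) {
      observed <- vapply(per_list, `[[`, 0L, "distinct_peaks")
      expected <- vapply(lists, function(gl) {
        expected_count(nrow(peaks), genome, gl, window = params$window,
                       merge_windows = params$merge_windows)
      }, 0)
      rep <- stage("enrich", enrichment_test(observed, expected))
      jsonlite::write_json(
        list(per_list = rep$per_list, joint = rep$joint),
        file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
      note("enrich", "run", list(fold = as.list(setNames(rep$per_list$fold,
                                                         rep$per_list$list)),
                                 joint_p = rep$joint$p_value))
    } else note("enrich", "skipped")

    hists <- stage("histogram", lapply(lists, function(gl) {
      tss_histogram(peaks, gl, range = params$window,
                    bin_width = params$bin_width)
    }))
    hist_df <- do.call(rbind, lapply(names(hists), function(lb) {
      h <- hists[[lb]]
      data.frame(list_label = lb,
                 bin_start = utils::head(h$bin_edges, -1),
                 bin_end = utils::tail(h$bin_edges, -1),
                 count = h$counts, stringsAsFactors = FALSE)
    }))
    utils::write.table(hist_df, file.path(out_dir, "tss_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("histogram", "run")
  } else {
    note("annotate", "skipped"); note("enrich", "skipped")
    note("histogram", "skipped")
  }

  if (!is.null(peaks) && !is.null(config$peaks_b)) {
    b <- stage("overlap", read_bed(config$peaks_b))
    c_set <- if (!is.null(config$peaks_c)) stage("overlap", read_bed(config$peaks_c))
    ov <- stage("overlap", overlap_summary(peaks, b, c_set))
    jsonlite::write_json(unclass(ov), file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    note("overlap", "run", list(fraction_a_in_b = ov$fraction_a_in_b,
                                triple = ov$triple))
  } else note("overlap", "skipped")

  if (!is.null(config$fasta)) {
    seqs <- stage("scan", read_fasta(config$fasta))
    if (!is.null(params$motif)) {
      hits <- stage("scan", do.call(rbind, lapply(names(seqs), function(id) {
        h <- scan_motif(seqs[[id]], params$motif)
        if (nrow(h)) cbind(seq_id = id, h) else NULL
      })))
      if (is.null(hits)) {
        hits <- data.frame(seq_id = character(0), offset = integer(0),
                           strand = character(0), matched = character(0))
      }
      utils::write.table(hits, file.path(out_dir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("scan", "run", list(n_hits = nrow(hits)))

      ce <- stage("centrimo", central_enrichment(seqs, params$motif,
                                                 central_width = params$central_width))
      jsonlite::write_json(unclass(ce), file.path(out_dir, "central_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      note("centrimo", "run", list(p_value = ce$p_value))

      sp <- stage("spamo", spaced_pair(seqs, params$motif, params$motif,
                                       max_gap = params$max_gap))
      jsonlite::write_json(
        list(counts = as.list(sp$counts), best_gap = sp$best_gap,
             p_value = sp$p_value),
        file.path(out_dir, "spaced_pair.json"), auto_unbox = TRUE, digits = NA)
      note("spamo", "run", list(best_gap = sp$best_gap, p_value = sp$p_value))
    } else {
      note("scan", "skipped"); note("centrimo", "skipped")
      note("spamo", "skipped")
    }
    negatives <- if (!is.null(config$fasta_negatives)) {
      stage("discover", read_fasta(config$fasta_negatives))
    } else {
      shuffle_sequences(seqs, seed = params$seed)
    }
    disc <- stage("discover", discover_motifs(seqs, negatives,
                                              k_range = params$k_min:params$k_max))
    utils::write.table(as.data.frame(disc),
                       file.path(out_dir, "discovered_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("discover", "run",
         list(top_motif = if (nrow(disc)) disc$iupac[1] else NA))
  } else {
    note("scan", "skipped"); note("centrimo", "skipped")
    note("spamo", "skipped"); note("discover", "skipped")
  }

  summary$timing <- list(wall_clock_sec =
                           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(summary)
}
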