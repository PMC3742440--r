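#' Genome model
#'
#' A minimal genome description: named chromosome lengths and their total.
#' Used to anchor peak coordinates and as the denominator of the uniform
#' background model (peak density = peaks / genome size).
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'   Names must be unique, lengths positive.
#' @return An object of class `genome_model` with elements `chrom_sizes`
#'   and `total_size`.
#' @examples
#' rat <- genome_model(c(chr1 = 2.75e9))
#' rat$total_size
#' @export
genome_model <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "") ||
      anyDuplicated(names(chrom_sizes))) {
    stop("chrom_sizes must have unique, non-empty names")
  }
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be finite and > 0")
  }
  structure(
    list(chrom_sizes = chrom_sizes, total_size = sum(chrom_sizes)),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %.4g bp total\n",
              length(x$chrom_sizes), x$total_size))
  invisible(x)
}

#' Peak set
#'
#' A labelled, ordered collection of genomic intervals (BED convention:
#' 0-based, half-open). Backed by a data frame with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand`, `extra`.
#' `score` is `NA` when absent in the source; `strand` is `"."` when
#' unstranded; `extra` carries any BED columns beyond the sixth verbatim.
#'
#' @param df Data frame with at least `chrom`, `start`, `end`.
#' @param label Condition name (e.g. `"treatment"`).
#' @param genome Optional [genome_model()] the intervals must fit on.
#' @param n_cols Number of BED columns represented (3--6+), used for
#'   faithful writing; inferred from present columns when `NULL`.
#' @return An object of class `peak_set` (a data frame subclass).
#' @export
peak_set <- function(df, label = "peaks", genome = NULL, n_cols = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$name))   df$name   <- if (nrow(df)) paste0("peak_", seq_len(nrow(df))) else character(0)
  if (is.null(df$score))  df$score  <- rep(NA_real_, nrow(df))
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  if (is.null(df$extra))  df$extra  <- rep(NA_character_, nrow(df))
  df <- df[c("chrom", "start", "end", "name", "score", "strand", "extra")]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  if (is.null(n_cols)) n_cols <- 6L
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_model"))
    bad <- !(df$chrom %in% names(genome$chrom_sizes))
    if (any(bad)) {
      stop("chromosome(s) not in genome: ",
           paste(unique(df$chrom[bad]), collapse = ", "))
    }
    over <- df$end > genome$chrom_sizes[df$chrom]
    if (any(over)) {
      stop("interval(s) extend past chromosome end: ",
           paste(utils::head(df$name[over], 3), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(df,
            class = c("peak_set", "data.frame"),
            label = label, genome = genome, n_cols = as.integer(n_cols))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> '%s': %d interval(s)\n", attr(x, "label"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Gene list
#'
#' A labelled collection of transcripts with strand-aware TSS and gene-body
#' coordinates (0-based; body half-open `[tx_start, tx_end)`). For a
#' plus-strand gene the TSS is `tx_start`; for a minus-strand gene it is
#' `tx_end - 1`.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tx_start`, `tx_end`.
#' @param label Cell-type name (e.g. `"oligodendrocyte"`).
#' @return An object of class `gene_list` (a data frame subclass).
#' @export
gene_list <- function(df, label = "genes") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tx_start", "tx_end")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("tss", "tx_start", "tx_end")) df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id within list '", label, "': ",
         df$gene_id[anyDuplicated(df$gene_id)])
  }
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  bad <- df$tx_start >= df$tx_end
  if (any(bad)) stop("tx_start must be < tx_end (gene ", df$gene_id[bad][1], ")")
  bad <- df$tss < df$tx_start | df$tss >= df$tx_end
  if (any(bad)) stop("tss outside [tx_start, tx_end) for gene ", df$gene_id[bad][1])
  bad <- ifelse(df$strand == "+", df$tss != df$tx_start, df$tss != df$tx_end - 1)
  if (any(bad)) {
    stop("tss inconsistent with strand for gene ", df$gene_id[bad][1],
         " (+: tss == tx_start; -: tss == tx_end - 1)")
  }
  rownames(df) <- NULL
  structure(df, class = c("gene_list", "data.frame"), label = label)
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s': %d gene(s)\n", attr(x, "label"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
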