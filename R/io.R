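#' Read a BED file of peak intervals
#'
#' Reads BED3--BED6+ (tab-separated, UCSC dialect). `track`, `browser` and
#' `#` comment lines are skipped. Coordinates are kept 0-based half-open.
#' Columns 4--6 populate name/score/strand when present; columns beyond the
#' sixth are preserved verbatim in `extra` so that [write_bed()] round-trips
#' the file.
#'
#' @param path Path to the BED file.
#' @param genome Optional [genome_model()]; intervals on chromosomes absent
#'   from it, or extending past a chromosome end, are an error.
#' @param label Condition label attached to the returned set; defaults to
#'   the file name without extension.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, genome = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 tab-separated columns")
  }
  n <- length(fields)
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- getcol(1)
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) stop("line ", idx[which(bad)[1]], ": non-integer coordinates")
  bad <- start < 0 | start >= end
  if (any(bad)) stop("line ", idx[which(bad)[1]], ": requires 0 <= start < end")
  name <- getcol(4)
  if (n) name[is.na(name)] <- paste0("peak_", which(is.na(name)))
  score <- suppressWarnings(as.numeric(getcol(5)))
  strand <- getcol(6)
  strand[is.na(strand)] <- "."
  bad <- !(strand %in% c("+", "-", "."))
  if (any(bad)) stop("line ", idx[which(bad)[1]], ": invalid strand")
  extra <- vapply(fields, function(f) {
    if (length(f) > 6) paste(f[-(1:6)], collapse = "\t") else NA_character_
  }, "")
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, extra = extra,
                   stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    missing_chr <- !(chrom %in% names(genome$chrom_sizes))
    if (any(missing_chr)) {
      stop("line ", idx[which(missing_chr)[1]], ": chromosome '",
           chrom[which(missing_chr)[1]], "' not in genome")
    }
  }
  peak_set(df, label = label, genome = genome,
           n_cols = if (n) max(pmin(nf, 6L)) else 3L)
}

#' Write a peak set as BED
#'
#' Emits as many columns as the source had (tracked on the [peak_set()]),
#' so a canonical 6-column BED read by [read_bed()] is reproduced
#' byte-for-byte; `extra` payload columns are appended verbatim.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  n_cols <- attr(peaks, "n_cols") %||% 6L
  fmt_num <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) "." else if (v == floor(v)) sprintf("%d", as.integer(v))
      else format(v, trim = TRUE, scientific = FALSE)
    }, "")
  }
  cols <- list(peaks$chrom, fmt_num(peaks$start), fmt_num(peaks$end))
  if (n_cols >= 4) cols <- c(cols, list(peaks$name))
  if (n_cols >= 5) cols <- c(cols, list(fmt_num(peaks$score)))
  if (n_cols >= 6) cols <- c(cols, list(peaks$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  has_extra <- !is.na(peaks$extra)
  lines[has_extra] <- paste(lines[has_extra], peaks$extra[has_extra], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene table
#'
#' A TSV with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `tx_start`, `tx_end`, `list_label`. Rows are grouped by `list_label`
#' into [gene_list()] objects; all gene-record invariants (TSS within the
#' body and consistent with the strand, unique ids per list) are enforced.
#'
#' @param path Path to the TSV.
#' @return Named list of [gene_list()] objects, one per label, in order of
#'   first appearance.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tx_start", "tx_end", "list_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) return(structure(list(), names = character(0)))
  labels <- unique(df$list_label)
  out <- lapply(labels, function(lb) {
    gene_list(df[df$list_label == lb, need[1:6], drop = FALSE], label = lb)
  })
  names(out) <- labels
  out
}

#' Write gene lists as a gene table TSV
#'
#' @param lists A list of [gene_list()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(lists, path) {
  if (inherits(lists, "gene_list")) lists <- list(lists)
  rows <- lapply(lists, function(gl) {
    df <- as.data.frame(gl)
    df$list_label <- attr(gl, "label")
    df
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Sequences are uppercased; only A, C, G, T, N are accepted (ambiguity
#' codes beyond N, or RNA letters, are rejected naming the offending
#' record). Empty records are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("failed to parse FASTA: ", conditionMessage(e)))
  seqs <- toupper(as.character(ss))
  ids <- names(ss)
  if (any(!nzchar(seqs))) stop("empty record: ", ids[which(!nzchar(seqs))[1]])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character (only A/C/G/T/N allowed) in record: ",
         ids[which(bad)[1]])
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
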