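# Brute-force oracles kept deliberately independent of the package's
# indexed/Biostrings-backed implementations.

# all-pairs overlap flags: query i flagged iff any subject shares >= 1 bp
oracle_overlap_flags <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          query$start[i] < subject$end &
          subject$start < query$end[i])
  }, TRUE)
}

# test every offset of every expansion of the motif, both strands
oracle_scan <- function(sequence, motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  words <- expand_iupac(motif)
  m <- nchar(motif)
  L <- nchar(sequence)
  out <- data.frame(offset = integer(0), strand = character(0),
                    matched = character(0), stringsAsFactors = FALSE)
  if (L < m) return(out)
  for (o in 0:(L - m)) {
    win <- substr(sequence, o + 1, o + m)
    if (grepl("N", win, fixed = TRUE)) next
    if (win %in% words) {
      out <- rbind(out, data.frame(offset = o, strand = "+", matched = win,
                                   stringsAsFactors = FALSE))
    }
    if (rc(win) %in% words) {
      out <- rbind(out, data.frame(offset = o, strand = "-",
                                   matched = rc(win), stringsAsFactors = FALSE))
    }
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_peak_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                           max_width = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T", "N"), L,
                                       replace = TRUE,
                                       prob = c(.24, .24, .24, .24, .04)),
                                collapse = "")

random_iupac <- function(m) {
  paste(sample(c("A", "C", "G", "T", "R", "Y", "S", "W"), m, replace = TRUE,
               prob = c(rep(.2, 4), rep(.05, 4))), collapse = "")
}

make_gene <- function(chrom = "chr1", strand = "+", tss = 1e6,
                      len = 5000, id = "g1") {
  if (strand == "+") {
    data.frame(gene_id = id, chrom = chrom, strand = strand, tss = tss,
               tx_start = tss, tx_end = tss + len, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = id, chrom = chrom, strand = strand, tss = tss,
               tx_start = tss - len + 1, tx_end = tss + 1,
               stringsAsFactors = FALSE)
  }
}
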