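iupac_from_letters <- function(letters) {
  sets <- vapply(Biostrings::IUPAC_CODE_MAP,
                 function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
  key <- paste(sort(unique(letters)), collapse = "")
  code <- names(sets)[sets == key]
  if (!length(code)) stop("no IUPAC code for letter set: ", key)
  code
}

# one-sided Fisher (hypergeometric upper tail) for enrichment in positives:
# a of n_pos positive and b of n_neg negative sequences contain the motif
fisher_enrichment_p <- function(a, b, n_pos, n_neg) {
  stats::phyper(a - 1, n_pos, n_neg, a + b, lower.tail = FALSE)
}

# which sequences contain >= 1 valid (no-N-window) match on either strand
contains_motif <- function(seqs, motif) {
  if (!length(seqs)) return(logical(0))
  ss <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::vcountPattern(motif, ss, fixed = "subject")
  rc <- revcomp(motif)
  if (rc != motif) cnt <- cnt + Biostrings::vcountPattern(rc, ss, fixed = "subject")
  hit <- cnt > 0
  recheck <- which(hit & grepl("N", seqs, fixed = TRUE))
  for (i in recheck) hit[i] <- nrow(scan_motif(seqs[i], motif)) > 0
  hit
}

# replace every matched window (either strand) with Ns
mask_motif <- function(seqs, motif) {
  m <- nchar(motif)
  vapply(seqs, function(s) {
    hits <- scan_motif(s, motif)
    for (o in hits$offset) substr(s, o + 1L, o + m) <- strrep("N", m)
    s
  }, "", USE.NAMES = FALSE)
}

# per-sequence presence of every canonical k-mer (strand-collapsed:
# a k-mer and its reverse complement are one candidate; N-containing
# windows are skipped). Returns list of character vectors.
canonical_kmer_sets <- function(seqs, k) {
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- unique(substring(s, 1:(n - k + 1), k:n))
    km[!grepl("N", km, fixed = TRUE)]
  })
  u <- unique(unlist(per_seq, use.names = FALSE))
  if (!length(u)) return(per_seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
  canon <- setNames(pmin(u, rc), u)
  lapply(per_seq, function(km) unique(unname(canon[km])))
}

count_sets <- function(sets, levels) {
  tabulate(factor(unlist(sets, use.names = FALSE), levels = levels),
            nbins = length(levels))
}

#' Discriminative k-mer motif discovery
#'
#' A desk-scale discriminative search in the spirit of DREME: every exact
#' k-mer (k in `k_range`, strand-collapsed) is scored by a one-sided Fisher
#' exact test for enrichment in positive over negative sequences; each of
#' the top exact words is then generalized by merging, at a single
#' position, top words differing only there (e.g. CTGGCAC + CTGGTAC ->
#' CTGGYAC) whenever the merge improves the p-value, and the best result
#' overall is reported. The reported E-value is the Fisher p
#' multiplied by the number of candidates evaluated (a Bonferroni-style
#' surrogate). After a motif is reported, its occurrences are masked with
#' Ns in both sets and a further round is run.
#'
#' @param positives,negatives Character vectors of sequences over A/C/G/T/N.
#' @param k_range Integer vector of word lengths (default 6:8).
#' @param rounds Number of report-and-mask rounds (default 2).
#' @param top_merge Number of top exact words considered as merge partners.
#' @param n_seeds Number of top exact words used as generalization seeds.
#' @return Data frame of class `discovered_motifs`, sorted by `e_value`:
#'   `iupac`, `pos_count`, `neg_count`, `fisher_p`, `e_value`,
#'   `n_candidates`, `round`.
#' @export
discover_motifs <- function(positives, negatives, k_range = 6:8,
                            rounds = 2, top_merge = 50, n_seeds = 10) {
  if (!length(positives) || !length(negatives)) {
    stop("both sequence sets must be non-empty")
  }
  positives <- toupper(positives)
  negatives <- toupper(negatives)
  n_pos <- length(positives)
  n_neg <- length(negatives)
  out <- list()
  for (round in seq_len(rounds)) {
    cand <- character(0)
    a <- integer(0)
    b <- integer(0)
    kk <- integer(0)
    for (k in k_range) {
      pos_sets <- canonical_kmer_sets(positives, k)
      neg_sets <- canonical_kmer_sets(negatives, k)
      lev <- unique(unlist(pos_sets, use.names = FALSE))
      if (!length(lev)) next
      cand <- c(cand, lev)
      a <- c(a, count_sets(pos_sets, lev))
      b <- c(b, count_sets(neg_sets, lev))
      kk <- c(kk, rep(k, length(lev)))
    }
    if (!length(cand)) break
    n_candidates <- length(cand)
    p <- fisher_enrichment_p(a, b, n_pos, n_neg)
    ord <- order(p, -a, cand)

    # generalize each of the top exact words by merging, at one position,
    # same-length words that differ only there; keep the overall best
    generalize <- function(seed_i) {
      seed <- list(iupac = cand[seed_i], a = a[seed_i], b = b[seed_i],
                   p = p[seed_i])
      k_seed <- kk[seed_i]
      top <- ord[kk[ord] == k_seed]
      top <- utils::head(top[top != seed_i], top_merge)
      base <- strsplit(seed$iupac, "")[[1]]
      partners <- list()
      for (j in top) {
        for (w in unique(c(cand[j], revcomp(cand[j])))) {
          wl <- strsplit(w, "")[[1]]
          diff <- which(wl != base)
          if (length(diff) == 1) {
            partners[[length(partners) + 1L]] <-
              list(pos = diff, letter = wl[diff], p = p[j])
          }
        }
      }
      best <- seed
      if (length(partners)) {
        by_pos <- split(partners, vapply(partners, `[[`, 0L, "pos"))
        for (grp in by_pos) {
          pos <- grp[[1]]$pos
          grp <- grp[order(vapply(grp, `[[`, 0, "p"))]
          letters <- base[pos]
          cur <- seed
          for (g in grp) {
            trial_letters <- unique(c(letters, g$letter))
            trial <- base
            trial[pos] <- iupac_from_letters(trial_letters)
            motif <- paste(trial, collapse = "")
            ta <- sum(contains_motif(positives, motif))
            tb <- sum(contains_motif(negatives, motif))
            tp <- fisher_enrichment_p(ta, tb, n_pos, n_neg)
            if (tp < cur$p) {
              cur <- list(iupac = motif, a = ta, b = tb, p = tp)
              letters <- trial_letters
            } else break
          }
          if (cur$p < best$p) best <- cur
        }
      }
      best
    }
    seeds <- utils::head(ord, n_seeds)
    results <- lapply(seeds, generalize)
    best <- results[[which.min(vapply(results, `[[`, 0, "p"))]]
    out[[round]] <- data.frame(
      iupac = best$iupac, pos_count = best$a, neg_count = best$b,
      fisher_p = best$p, e_value = best$p * n_candidates,
      n_candidates = n_candidates, round = round, stringsAsFactors = FALSE
    )
    if (round < rounds) {
      positives <- mask_motif(positives, best$iupac)
      negatives <- mask_motif(negatives, best$iupac)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(iupac = character(0), pos_count = integer(0),
               neg_count = integer(0), fisher_p = numeric(0),
               e_value = numeric(0), n_candidates = integer(0),
               round = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$e_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("discovered_motifs", "data.frame")
  res
}
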