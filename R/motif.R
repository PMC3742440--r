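IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1 || !nzchar(motif)) {
    stop("motif must be a single non-empty string")
  }
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1]]
  bad <- !(letters %in% names(IUPAC_COMPLEMENT))
  if (any(bad)) stop("invalid IUPAC letter in motif: ", letters[bad][1])
  motif
}

#' Expand an IUPAC consensus into its exact m-mers
#'
#' Cartesian expansion of every degenerate position (Y = C/T, W = A/T, ...).
#'
#' @param motif IUPAC consensus string.
#' @return Character vector of all exact sequences matching the consensus.
#' @examples
#' expand_iupac("CTGGYAC")
#' @export
expand_iupac <- function(motif) {
  motif <- check_motif(motif)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]], "")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[rev(seq_along(sets))], 1, paste, collapse = ""))
}

#' Reverse complement of an IUPAC string
#'
#' IUPAC-aware (Y <-> R, W <-> W, ...); an involution.
#'
#' @param seq Character vector of IUPAC strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- check_motif(s)
    paste(rev(IUPAC_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Forward-strand match starts (1-based) of an IUPAC motif in one sequence.
# N in the subject never matches (hits whose window contains N are dropped).
match_starts <- function(sequence, motif) {
  m <- nchar(motif)
  if (nchar(sequence) < m) return(integer(0))
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(sequence),
    fixed = "subject"
  )
  starts <- BiocGenerics::start(hits)
  if (length(starts)) {
    win <- substring(sequence, starts, starts + m - 1L)
    starts <- starts[!grepl("N", win, fixed = TRUE)]
  }
  starts
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every offset where the forward window matches the motif and,
#' when `both_strands`, every offset where the reverse complement of the
#' window matches (a minus-strand hit). Overlapping hits are all reported;
#' order is deterministic by (offset, strand) with `+` before `-`. `N` in
#' the sequence never matches any motif letter. A sequence shorter than
#' the motif yields an empty result.
#'
#' @param sequence Single string over A/C/G/T/N.
#' @param motif IUPAC consensus.
#' @param both_strands Scan the minus strand too (default TRUE)?
#' @return Data frame with `offset` (0-based position of the match's first
#'   base in forward coordinates), `strand`, and `matched` (the m-mer as
#'   read on the hit strand).
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  motif <- check_motif(motif)
  sequence <- toupper(sequence)
  m <- nchar(motif)
  fwd <- match_starts(sequence, motif)
  res <- data.frame(offset = fwd - 1L, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev_starts <- match_starts(sequence, revcomp(motif))
    res <- rbind(res, data.frame(offset = rev_starts - 1L,
                                 strand = rep("-", length(rev_starts)),
                                 stringsAsFactors = FALSE))
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  if (nrow(res)) {
    win <- substring(sequence, res$offset + 1L, res$offset + m)
    res$matched <- ifelse(res$strand == "+", win, revcomp(win))
  } else {
    res$matched <- character(0)
  }
  rownames(res) <- NULL
  res
}

#' Central enrichment of a motif in fixed-length sequences
#'
#' For each sequence with at least one hit (either strand), the best hit is
#' the one whose center is closest to the sequence center (ties: `+`
#' strand, then leftmost). The number of sequences whose best hit falls in
#' a central window of width `central_width` is compared with a binomial
#' null in which the hit center is uniform over the possible placements:
#' `null_prob` = central placements / (L - m + 1), and the p-value is the
#' one-sided upper tail P(X >= n_central). With no hit-bearing sequences
#' the p-value is 1 by convention.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param motif IUPAC consensus.
#' @param central_width Width of the central window in bp.
#' @param best_site_only Use only the best hit per sequence (default); with
#'   `FALSE` every hit contributes one Bernoulli trial.
#' @return A `central_enrichment`: list with `n_sequences_with_hit`,
#'   `n_central`, `central_width`, `null_prob`, `p_value`.
#' @export
central_enrichment <- function(sequences, motif, central_width = 100,
                               best_site_only = TRUE) {
  motif <- check_motif(motif)
  L <- unique(nchar(sequences))
  if (length(L) > 1) stop("sequences must all have the same length")
  m <- nchar(motif)
  if (central_width >= L) stop("central_width must be < sequence length")
  # hit with 0-based offset o has center o + m/2; offsets run 0 .. L - m
  offsets <- 0:(L - m)
  centers <- offsets + m / 2
  is_central <- abs(centers - L / 2) <= central_width / 2
  null_prob <- sum(is_central) / (L - m + 1)
  n_with_hit <- 0L
  n_central <- 0L
  n_trials <- 0L
  for (s in sequences) {
    hits <- scan_motif(s, motif, both_strands = TRUE)
    if (!nrow(hits)) next
    n_with_hit <- n_with_hit + 1L
    if (best_site_only) {
      dist <- abs(hits$offset + m / 2 - L / 2)
      ord <- order(dist, hits$strand != "+", hits$offset)
      best <- hits[ord[1], ]
      n_trials <- n_trials + 1L
      n_central <- n_central + as.integer(abs(best$offset + m / 2 - L / 2) <= central_width / 2)
    } else {
      n_trials <- n_trials + nrow(hits)
      n_central <- n_central + sum(abs(hits$offset + m / 2 - L / 2) <= central_width / 2)
    }
  }
  p <- if (n_trials == 0) 1 else
    stats::pbinom(n_central - 1, n_trials, null_prob, lower.tail = FALSE)
  structure(list(n_sequences_with_hit = n_with_hit, n_central = n_central,
                 n_trials = n_trials, central_width = central_width,
                 null_prob = null_prob, p_value = p),
            class = "central_enrichment")
}

#' @export
print.central_enrichment <- function(x, ...) {
  cat(sprintf("<central_enrichment> %d/%d best hits central (width %d, null %.3g): p = %.3g\n",
              x$n_central, x$n_sequences_with_hit, x$central_width,
              x$null_prob, x$p_value))
  invisible(x)
}

#' Spaced co-occurrence of two motifs
#'
#' Counts, over all sequences, pairs of a primary and a secondary hit on
#' the same sequence separated by a gap of g bases strictly between the
#' two matched m-mers (either side), for g in 0..`max_gap`. Overlapping
#' pairs (negative gap) are excluded. When the two motifs are identical,
#' each unordered hit pair is counted once (leftmost hit as primary). The
#' null is uniform over the `max_gap + 1` gap bins; the p-value is the
#' binomial upper tail for the count at the best gap, Bonferroni-adjusted
#' by the number of gaps and capped at 1.
#'
#' @param sequences Character vector of sequences.
#' @param primary,secondary IUPAC consensus motifs.
#' @param max_gap Largest gap considered (default 10).
#' @return A `spacing_report`: list with `counts` (named by gap),
#'   `n_pairs`, `best_gap`, `best_count`, `p_value`.
#' @export
spaced_pair <- function(sequences, primary, secondary, max_gap = 10) {
  stopifnot(max_gap >= 0)
  primary <- check_motif(primary)
  secondary <- check_motif(secondary)
  same <- primary == secondary
  m1 <- nchar(primary); m2 <- nchar(secondary)
  counts <- integer(max_gap + 1)
  for (s in sequences) {
    ph <- scan_motif(s, primary)$offset
    sh <- if (same) ph else scan_motif(s, secondary)$offset
    if (!length(ph) || !length(sh)) next
    for (p in ph) {
      # gap with secondary to the right of the primary; when the motifs are
      # identical this canonical order counts each unordered pair once
      gaps <- sh - (p + m1)
      if (!same) gaps <- c(gaps, p - (sh + m2))
      gaps <- gaps[gaps >= 0 & gaps <= max_gap]
      if (length(gaps)) {
        counts <- counts + tabulate(gaps + 1L, nbins = max_gap + 1L)
      }
    }
  }
  n_pairs <- sum(counts)
  best_gap <- which.max(counts) - 1L
  p <- if (n_pairs == 0) 1 else min(1, (max_gap + 1) *
    stats::pbinom(counts[best_gap + 1L] - 1, n_pairs, 1 / (max_gap + 1),
                  lower.tail = FALSE))
  structure(list(counts = setNames(counts, 0:max_gap), n_pairs = n_pairs,
                 best_gap = best_gap, best_count = counts[best_gap + 1L],
                 p_value = p),
            class = "spacing_report")
}

#' @export
print.spacing_report <- function(x, ...) {
  cat(sprintf("<spacing_report> %d pairs; best gap %d (%d pairs), adjusted p = %.3g\n",
              x$n_pairs, x$best_gap, x$best_count, x$p_value))
  invisible(x)
}
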