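# Heuristic cloverleaf tRNA detector.
#
# Real tRNA annotation uses covariance models; here a geometric heuristic
# is enough because the scientific question is only whether a
# suppressor-anticodon tRNA is present, and the detector's contract is
# validated against generator-built canonical cassettes.
#
# Window layout (1-based within a window of length w, anticodon-arm start
# a in 23..min(39, w - 45)):
#   acceptor stem : positions 1..7 paired with w-6..w       (7 pairs)
#   D-arm stem    : a-17..a-14 paired with a-5..a-2         (4 pairs)
#   anticodon arm : stem a..a+4 / a+12..a+16, loop a+5..a+11 (5 pairs),
#                   anticodon at loop positions 3-5 = a+7..a+9
#   T-arm stem    : a+22..a+26 paired with a+34..a+38       (5 pairs),
#                   T loop a+27..a+33 opening with the TTC motif
# structure_score = total paired positions across the four stems (max 21).
# Watson-Crick and GU (here GT) pairs both count.  The TTC (T-psi-C)
# motif requirement is what keeps the false-positive rate down: stem
# complementarity alone arises constantly by chance in 30-kb genomes.

.pair_ok <- local({
  m <- matrix(FALSE, 5, 5)
  ok <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  m[ok] <- TRUE
  m
})

.pair_count <- function(v, i, off5, off3, k) {
  # v: encoded seq (1..4, 5 = ambiguous); i: vector of window starts.
  # counts pairs (i + off5 + j) vs (i + off3 - j), j = 0..k-1
  total <- integer(length(i))
  for (j in 0:(k - 1L)) {
    a <- v[i + off5 + j]
    b <- v[i + off3 - j]
    total <- total + .pair_ok[cbind(a, b)]
  }
  total
}

#' Configuration for the tRNA detector
#'
#' @param min_window,max_window Window lengths scanned, in nt (60-100 by
#'   default; all four arms only fit from 68 nt up).
#' @param min_score Minimum structure score (total paired positions over
#'   the four stems, max 21) to report a hit (default 16).
#' @return List of class `trna_config`.
#' @export
trna_config <- function(min_window = 60L, max_window = 100L,
                        min_score = 16L) {
  stopifnot(min_window >= 50L, max_window >= min_window, min_score >= 1L)
  structure(list(min_window = as.integer(min_window),
                 max_window = as.integer(max_window),
                 min_score = as.integer(min_score)),
            class = "trna_config")
}

#' Classify a tRNA anticodon as a stop-codon suppressor
#'
#' The decoded codon is the reverse complement of the anticodon (both in
#' the DNA alphabet): a CTA anticodon reads the amber stop TAG, TCA reads
#' the opal stop TGA, TTA reads the ochre stop TAA; anything else is a
#' sense anticodon.
#'
#' @param anticodon 3-mer DNA string, 5'->3'.
#' @return One of `"amber"`, `"opal"`, `"ochre"`, `"none"`.
#' @examples
#' classify_suppressor("CTA")  # amber
#' @export
classify_suppressor <- function(anticodon) {
  anticodon <- toupper(anticodon)
  if (nchar(anticodon) != 3L ||
      !all(strsplit(anticodon, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("anticodon must be a 3-mer over A/C/G/T", call. = FALSE)
  }
  switch(reverse_complement(anticodon),
         TAG = "amber", TGA = "opal", TAA = "ochre", "none")
}

#' Detect tRNA-like loci on both strands
#'
#' Slides windows of `min_window`..`max_window` nt over the sequence and
#' its reverse complement, requiring an acceptor stem (>= 5 of 7 pairs
#' between the window ends), a D-arm stem (>= 3 of 4), an anticodon-arm
#' stem (>= 4 of 5 flanking a 7-nt loop) and a T-arm stem (>= 4 of 5,
#' with a T loop opening on the canonical TTC motif) at canonical offsets
#' from the anticodon arm, whose start is searched 22-38 nt from the
#' window 5' end.  Hits with structure score at or above
#' `config$min_score` are reported after greedy deduplication by
#' coordinate overlap (higher score kept, ties to the leftmost).
#'
#' @param seq DNA string.
#' @param config A [trna_config()].
#' @param contig_id Identifier for the output.
#' @return Data.frame with `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `anticodon` (coding strand,
#'   DNA), `decoded_codon`, `suppressor_class`, `structure_score`.
#' @export
find_trnas <- function(seq, config = trna_config(), contig_id = "contig") {
  seq <- toupper(seq)
  L <- nchar(seq)
  hits <- rbind(
    .scan_trna_strand(seq, config),
    {
      h <- .scan_trna_strand(reverse_complement(seq), config)
      if (nrow(h) > 0L) {
        s <- h$start
        h$start <- L - h$end
        h$end <- L - s
        h$strand <- "-"
      }
      h
    }
  )
  if (nrow(hits) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      anticodon = character(0), decoded_codon = character(0),
                      suppressor_class = character(0),
                      structure_score = integer(0),
                      stringsAsFactors = FALSE))
  }
  # greedy dedup by overlap: best score first, leftmost on ties
  hits <- hits[order(-hits$structure_score, hits$start, hits$strand), ,
               drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- hits[keep, , drop = FALSE]
      if (any(pmin(prev$end, hits$end[i]) > pmax(prev$start, hits$start[i])))
        ok <- FALSE
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$contig_id <- contig_id
  hits$decoded_codon <- vapply(hits$anticodon, reverse_complement, "")
  hits$suppressor_class <- vapply(hits$anticodon, classify_suppressor, "")
  rownames(hits) <- NULL
  hits[, c("contig_id", "start", "end", "strand", "anticodon",
           "decoded_codon", "suppressor_class", "structure_score")]
}

.scan_trna_strand <- function(s, config) {
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), anticodon = character(0),
                      structure_score = integer(0), stringsAsFactors = FALSE)
  w_lo <- max(config$min_window, 68L)
  w_hi <- min(config$max_window, L)
  if (w_hi < w_lo) return(empty)
  enc <- .encode_seq(s) + 1L
  enc[is.na(enc)] <- 5L
  out <- list()
  for (w in w_lo:w_hi) {
    i <- seq_len(L - w + 1L)
    acc <- .pair_count(enc, i, 0L, w - 1L, 7L)
    cand <- i[acc >= 5L]
    if (length(cand) == 0L) next
    acc <- acc[acc >= 5L]
    best_score <- integer(length(cand))
    best_a <- integer(length(cand))
    for (a in 23:min(39L, w - 45L)) {
      dpr <- .pair_count(enc, cand, a - 18L, a - 3L, 4L)
      acp <- .pair_count(enc, cand, a - 1L, a + 15L, 5L)
      tpr <- .pair_count(enc, cand, a + 21L, a + 37L, 5L)
      ttc <- substring(s, cand + a + 26L, cand + a + 28L) == "TTC"
      ok <- dpr >= 3L & acp >= 4L & tpr >= 4L & ttc
      sc <- ifelse(ok, acc + dpr + acp + tpr, 0L)
      better <- sc > best_score
      best_score[better] <- sc[better]
      best_a[better] <- a
    }
    hit <- best_score >= config$min_score
    if (any(hit)) {
      ci <- cand[hit]
      aa <- best_a[hit]
      out[[length(out) + 1L]] <- data.frame(
        start = ci - 1L, end = ci - 1L + w, strand = "+",
        anticodon = substring(s, ci + aa + 6L, ci + aa + 8L),
        structure_score = best_score[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Re-check a reported tRNA hit against the stem rules
#'
#' Independent verifier for the detector's contract: recomputes the four
#' stem pair counts for the reported window and anticodon-arm placement
#' and confirms the minima and total score.
#'
#' @param seq The scanned sequence.
#' @param hit One row of a [find_trnas()] result.
#' @param config The [trna_config()] used.
#' @return TRUE if the hit satisfies the stated rules.
#' @export
verify_trna_hit <- function(seq, hit, config = trna_config()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (hit$strand == "-") {
    win <- reverse_complement(substr(seq, hit$start + 1L, hit$end))
  } else {
    win <- substr(seq, hit$start + 1L, hit$end)
  }
  w <- nchar(win)
  enc <- .encode_seq(win) + 1L
  enc[is.na(enc)] <- 5L
  pair <- function(off5, off3, k) {
    tot <- 0L
    for (j in 0:(k - 1L)) {
      tot <- tot + .pair_ok[enc[1L + off5 + j], enc[1L + off3 - j]]
    }
    tot
  }
  for (a in 23:min(39L, w - 45L)) {
    acc <- pair(0L, w - 1L, 7L)
    dpr <- pair(a - 18L, a - 3L, 4L)
    acp <- pair(a - 1L, a + 15L, 5L)
    tpr <- pair(a + 21L, a + 37L, 5L)
    if (acc >= 5L && dpr >= 3L && acp >= 4L && tpr >= 4L &&
        substring(win, a + 27L, a + 29L) == "TTC" &&
        acc + dpr + acp + tpr >= config$min_score &&
        substring(win, a + 7L, a + 9L) == hit$anticodon) {
      return(TRUE)
    }
  }
  FALSE
}

#' Dataset-level suppressor tRNA summary
#'
#' Reduces per-genome tRNA hits to counts and percentages of genomes
#' carrying at least one amber-suppressor and at least one
#' opal-suppressor tRNA.
#'
#' @param hits_per_genome List of [find_trnas()] results, one per genome.
#' @return Data.frame with rows `amber` and `opal`: `n_genomes_with_hit`,
#'   `n_genomes`, `pct` (one decimal).
#' @examples
#' # 375 of 715 genomes with an amber suppressor -> 52.4%
#' proportion_pct(375, 715)
#' @export
summarize_suppressors <- function(hits_per_genome) {
  n <- length(hits_per_genome)
  has <- function(cls) {
    sum(vapply(hits_per_genome, function(h)
      any(h$suppressor_class == cls), logical(1)))
  }
  k_amber <- has("amber")
  k_opal <- has("opal")
  data.frame(
    suppressor_class = c("amber", "opal"),
    n_genomes_with_hit = c(k_amber, k_opal),
    n_genomes = n,
    pct = c(proportion_pct(k_amber, n), proportion_pct(k_opal, n)),
    stringsAsFactors = FALSE
  )
}
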