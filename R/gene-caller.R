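#' Gene-caller configuration
#'
#' @param min_len_nt Minimum ORF length considered a gene candidate
#'   (default 90 nt, including the stop codon).
#' @param seed_min_len_nt Minimum ORF length used to seed model training
#'   (default 300 nt).
#' @param per_gene_penalty_bits Flat per-gene score penalty (default 6
#'   bits); raising it emulates a stricter ORF filter.
#' @param max_overlap_nt Maximum tolerated overlap between selected genes
#'   (default 30 nt, enough for common stop/start overlaps).
#' @param training_passes Number of self-training passes (default 2; the
#'   second pass retrains on the genes selected by the first).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_len_nt = 90L, seed_min_len_nt = 300L,
                          per_gene_penalty_bits = 6, max_overlap_nt = 30L,
                          training_passes = 2L) {
  stopifnot(min_len_nt >= 30L, min_len_nt %% 3L == 0L,
            seed_min_len_nt >= min_len_nt, per_gene_penalty_bits >= 0,
            max_overlap_nt >= 0L, training_passes >= 1L)
  structure(list(min_len_nt = as.integer(min_len_nt),
                 seed_min_len_nt = as.integer(seed_min_len_nt),
                 per_gene_penalty_bits = per_gene_penalty_bits,
                 max_overlap_nt = as.integer(max_overlap_nt),
                 training_passes = as.integer(training_passes)),
            class = "caller_config")
}

#' Select a consistent gene set by dynamic programming
#'
#' Keeps only positive-scoring candidates and maximizes total score over
#' subsets in which any two genes overlap by at most `max_overlap_nt`
#' (weighted interval scheduling).  Score ties resolve toward the set with
#' more genes, then toward earlier coordinates; the result is
#' deterministic.
#'
#' @param calls Data.frame with `start`, `end` and `score_bits` columns.
#' @param max_overlap_nt Pairwise overlap allowance in nucleotides.
#' @return The selected subset, ordered by `start`.
#' @export
select_genes <- function(calls, max_overlap_nt = 30L) {
  if (nrow(calls) == 0L) return(calls)
  pos <- calls[calls$score_bits > 0, , drop = FALSE]
  if (nrow(pos) == 0L) return(pos)
  o <- order(pos$end, pos$start)
  pos <- pos[o, , drop = FALSE]
  n <- nrow(pos)
  # p[i]: last j < i with end[j] <= start[i] + allowance
  p <- findInterval(pos$start + max_overlap_nt, pos$end)
  p <- pmin(p, seq_len(n) - 1L)
  score <- c(0, numeric(n))
  count <- c(0L, integer(n))
  take <- logical(n)
  for (i in seq_len(n)) {
    s_take <- score[p[i] + 1L] + pos$score_bits[i]
    c_take <- count[p[i] + 1L] + 1L
    s_skip <- score[i]
    c_skip <- count[i]
    if (s_take > s_skip + 1e-12 ||
        (abs(s_take - s_skip) <= 1e-12 && c_take > c_skip)) {
      score[i + 1L] <- s_take
      count[i + 1L] <- c_take
      take[i] <- TRUE
    } else {
      score[i + 1L] <- s_skip
      count[i + 1L] <- c_skip
    }
  }
  keep <- logical(n)
  i <- n
  while (i >= 1L) {
    if (take[i]) {
      keep[i] <- TRUE
      i <- p[i]
    } else {
      i <- i - 1L
    }
  }
  out <- pos[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call genes on a contig under a genetic code
#'
#' Composes the pipeline: six-frame ORF enumeration, self-trained hexamer
#' scoring, and dynamic-programming selection of a near-non-overlapping,
#' positive-scoring gene set.  Each maximal ORF contributes one candidate
#' per plausible in-frame start codon (all sharing the ORF's stop), so
#' the selection can shorten a gene whose stop-to-stop interval reaches
#' into its neighbour instead of dropping it; at most one start variant
#' per interval can survive selection.  With `training_passes >= 2` the
#' coding model is re-estimated from the first pass's selected genes,
#' which sharpens the coding/background contrast.
#'
#' @param seq Contig DNA string.
#' @param code A [genetic_code()] (or a table id accepted by it).
#' @param config A [caller_config()].
#' @param contig_id Identifier for the output.
#' @return A data.frame of class `gene_calls`: the selected ORFs with
#'   `score_bits` and `rank` (order along the contig).  The fitted
#'   `coding_model` is attached as attribute `model`.
#' @examples
#' ts <- generate_genome(generator_config(seed = 1, n_genes = 10))
#' calls <- call_genes(ts$seq, genetic_code(11))
#' head(calls)
#' @export
call_genes <- function(seq, code, config = caller_config(),
                       contig_id = "contig") {
  if (!inherits(code, "genetic_code")) code <- genetic_code(code)
  stopifnot(inherits(config, "caller_config"))
  seq <- toupper(seq)
  orfs <- find_orfs(seq, code, min_len_nt = config$min_len_nt,
                    contig_id = contig_id)
  model <- suppressWarnings(
    train_coding_model(seq, code, seed_min_len_nt = config$seed_min_len_nt))
  selected <- orfs[0, , drop = FALSE]
  selected$score_bits <- numeric(0)
  for (pass in seq_len(config$training_passes)) {
    if (pass > 1L) {
      if (nrow(selected) == 0L) break
      model <- suppressWarnings(
        train_coding_model(seq, code, training_orfs = selected))
    }
    scored <- .expand_start_variants(
      orfs, seq, code, model,
      per_gene_penalty_bits = config$per_gene_penalty_bits,
      min_len_nt = config$min_len_nt)
    selected <- select_genes(scored, max_overlap_nt = config$max_overlap_nt)
  }
  if (nrow(selected) > 0L) selected$rank <- seq_len(nrow(selected))
  else selected$rank <- integer(0)
  attr(selected, "model") <- model
  attr(selected, "config") <- config
  class(selected) <- c("gene_calls", "data.frame")
  selected
}

#' @export
print.gene_calls <- function(x, ...) {
  cat(sprintf("<gene_calls: %d genes under code %s>\n", nrow(x),
              if (nrow(x) > 0L) x$code_id[1] else "?"))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
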