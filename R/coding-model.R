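# Self-trained hexamer (dicodon) coding-potential model.
#
# Coding statistics are learned from the genome being annotated: in-frame
# hexamers (step 3) of long ORFs form the coding table, all overlapping
# hexamers of the contig and its reverse complement form the background.
# Scores are log2 odds, so gene scores are in bits.

.HEXN <- 4096L

# 1-based indices of hexamers at `starts` (1-based) in encoded vector v;
# NA where any base is ambiguous.
.hex_index <- function(v, starts) {
  if (length(starts) == 0L) return(integer(0))
  idx <- v[starts] * 1024L + v[starts + 1L] * 256L + v[starts + 2L] * 64L +
    v[starts + 3L] * 16L + v[starts + 4L] * 4L + v[starts + 5L] + 1L
  idx
}

.hex_counts <- function(v, step) {
  n <- length(v)
  if (n < 6L) return(integer(.HEXN))
  starts <- seq.int(1L, n - 5L, by = step)
  idx <- .hex_index(v, starts)
  tabulate(idx[!is.na(idx)], .HEXN)
}

# Coding-strand sequence of one ORF row, terminal stop codon removed for
# complete ORFs.
.orf_cds <- function(orf_row, seq) {
  s <- substr(seq, orf_row$start + 1L, orf_row$end)
  if (orf_row$strand == "-") s <- reverse_complement(s)
  if (isTRUE(orf_row$complete)) s <- substr(s, 1L, nchar(s) - 3L)
  s
}

#' Train a coding-potential model on a contig
#'
#' Fits log2-odds scores for all 4096 hexamers from the in-frame hexamer
#' usage of putative genes versus the whole-contig background.  Training
#' ORFs are all ORFs of at least `seed_min_len_nt` found under `code`;
#' alternatively an explicit set of training intervals (e.g. a previous
#' pass's selected genes) can be supplied.  Contigs shorter than 2 kb give
#' too little signal and fall back to a uniform (all-zero) model with a
#' warning, as does an empty training set.
#'
#' @param seq Contig DNA string.
#' @param code A [genetic_code()].
#' @param seed_min_len_nt Minimum ORF length used for training (default
#'   300 nt).
#' @param training_orfs Optional data.frame of ORFs/genes to train on
#'   instead of the seed scan.
#' @return An object of class `coding_model`.
#' @export
train_coding_model <- function(seq, code, seed_min_len_nt = 300L,
                               training_orfs = NULL) {
  seq <- toupper(seq)
  L <- nchar(seq)
  uniform <- function(why) {
    warning(sprintf("uniform coding model: %s", why), call. = FALSE)
    structure(list(hexamer_logodds = numeric(.HEXN), pseudocount = 1,
                   trained_on_nt = 0L, uniform = TRUE,
                   code_id = code$table_id),
              class = "coding_model")
  }
  if (L < 2000L) return(uniform("contig shorter than 2 kb"))
  if (is.null(training_orfs)) {
    training_orfs <- find_orfs(seq, code, min_len_nt = seed_min_len_nt,
                               contig_id = "train")
    training_orfs <-
      training_orfs[training_orfs$end - training_orfs$start >=
                      seed_min_len_nt, , drop = FALSE]
  }
  if (nrow(training_orfs) == 0L) return(uniform("no training ORFs"))

  coding <- integer(.HEXN)
  trained_nt <- 0L
  for (i in seq_len(nrow(training_orfs))) {
    cds <- .orf_cds(training_orfs[i, ], seq)
    v <- .encode_seq(cds)
    coding <- coding + .hex_counts(v, step = 3L)
    trained_nt <- trained_nt + nchar(cds)
  }
  v_fwd <- .encode_seq(seq)
  v_rev <- .encode_seq(reverse_complement(seq))
  background <- .hex_counts(v_fwd, 1L) + .hex_counts(v_rev, 1L)

  p_cod <- (coding + 1) / (sum(coding) + .HEXN)
  p_bg <- (background + 1) / (sum(background) + .HEXN)
  structure(list(hexamer_logodds = log2(p_cod / p_bg), pseudocount = 1,
                 trained_on_nt = trained_nt, uniform = FALSE,
                 code_id = code$table_id),
            class = "coding_model")
}

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf("<coding_model code %s, trained on %d nt%s>\n", x$code_id,
              x$trained_on_nt, if (x$uniform) ", uniform fallback" else ""))
  invisible(x)
}

#' Score ORFs under a coding model
#'
#' The score of an ORF is the sum of hexamer log2 odds over its in-frame
#' hexamers (step 3, coding strand, terminal stop excluded) minus a flat
#' per-gene penalty that suppresses short spurious ORFs.  Under a uniform
#' model every ORF scores exactly minus the penalty.
#'
#' @param orfs Data.frame as returned by [find_orfs()].
#' @param seq The contig the ORFs were found on.
#' @param model A [train_coding_model()] result.
#' @param per_gene_penalty_bits Flat penalty in bits (default 6).
#' @return `orfs` with a `score_bits` column appended.
#' @export
score_orfs <- function(orfs, seq, model, per_gene_penalty_bits = 6) {
  stopifnot(inherits(model, "coding_model"))
  seq <- toupper(seq)
  L <- nchar(seq)
  if (nrow(orfs) > 0L && (min(orfs$start) < 0L || max(orfs$end) > L)) {
    stop("ORF coordinates outside the sequence", call. = FALSE)
  }
  scores <- numeric(nrow(orfs))
  lo <- model$hexamer_logodds
  for (i in seq_len(nrow(orfs))) {
    v <- .encode_seq(.orf_cds(orfs[i, ], seq))
    if (length(v) >= 6L) {
      idx <- .hex_index(v, seq.int(1L, length(v) - 5L, by = 3L))
      idx <- idx[!is.na(idx)]
      scores[i] <- sum(lo[idx])
    }
  }
  orfs$score_bits <- scores - per_gene_penalty_bits
  orfs
}

# Expand each ORF into in-frame start-codon variants sharing its stop,
# scored by suffix sums of the hexamer walk.  A stop-to-stop interval can
# reach deep into the upstream gene once a stop codon is reassigned; the
# first-start ORF then conflicts with its neighbour and the selection DP
# would have to drop a whole gene.  Giving the DP one candidate per
# plausible start lets it trim instead (at most one variant per interval
# can be selected, because variants overlap each other by at least
# min_len_nt).
.expand_start_variants <- function(orfs, seq, code, model,
                                   per_gene_penalty_bits, min_len_nt) {
  lo <- model$hexamer_logodds
  re_codon <- if (is.null(code$reassignment)) NA_character_ else
    code$reassignment$codon
  n <- nrow(orfs)
  o_start <- orfs$start; o_end <- orfs$end; o_strand <- orfs$strand
  o_frame <- orfs$frame; o_complete <- orfs$complete
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    cds <- substr(seq, o_start[i] + 1L, o_end[i])
    if (o_strand[i] == "-") cds <- reverse_complement(cds)
    has_stop <- o_complete[i] ||
      substr(cds, nchar(cds) - 2L, nchar(cds)) %in% code$stop_set
    n_int <- nchar(cds) %/% 3L - if (has_stop) 1L else 0L
    if (n_int < 1L) next
    codons <- substring(cds, 3L * seq_len(n_int) - 2L, 3L * seq_len(n_int))
    # hexamer walk over internal codons, then suffix sums per start codon
    vals <- numeric(max(n_int - 1L, 0L))
    if (n_int >= 2L) {
      v <- .encode_seq(substr(cds, 1L, 3L * n_int))
      idx <- .hex_index(v, 3L * seq_len(n_int - 1L) - 2L)
      vals <- ifelse(is.na(idx), 0, lo[idx])
    }
    suffix <- rev(cumsum(rev(c(vals, 0))))
    is_start <- codons %in% code$start_set
    starts_j <- which(is_start)
    if (!o_complete[i] && !1L %in% starts_j) starts_j <- c(1L, starts_j)
    total_codons <- nchar(cds) %/% 3L
    starts_j <- starts_j[(total_codons - starts_j + 1L) * 3L >= min_len_nt]
    if (length(starts_j) == 0L) next
    trim <- 3L * (starts_j - 1L)
    re_suffix <- if (is.na(re_codon)) rep(0L, length(starts_j)) else
      as.integer(rev(cumsum(rev(codons == re_codon)))[starts_j])
    acc[[i]] <- list(
      start = if (o_strand[i] == "+") o_start[i] + trim else
        rep(o_start[i], length(trim)),
      end = if (o_strand[i] == "+") rep(o_end[i], length(trim)) else
        o_end[i] - trim,
      strand = rep(o_strand[i], length(trim)),
      frame = rep(o_frame[i], length(trim)),
      complete = has_stop & is_start[starts_j],
      n_re = re_suffix,
      score = suffix[starts_j] - per_gene_penalty_bits)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0L) {
    res <- .empty_orf_frame()
    res$score_bits <- numeric(0)
    return(res)
  }
  pull <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  res <- data.frame(
    contig_id = if (n > 0L) orfs$contig_id[1] else character(0),
    start = pull("start"), end = pull("end"), strand = pull("strand"),
    frame = pull("frame"), complete = pull("complete"),
    n_reassigned_in_frame = pull("n_re"),
    code_id = code$table_id, score_bits = pull("score"),
    stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
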