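#' Enumerate open reading frames under a genetic code
#'
#' Scans all six frames of `seq` for maximal open reading frames under the
#' stop set of `code`.  Within each stop-to-stop interval one ORF is
#' reported, running from the first in-frame start codon (ATG/GTG/TTG) to
#' and including the terminal stop.  Stop-free runs touching a contig edge
#' are reported as partial ORFs (`complete = FALSE`): the run upstream of
#' the first stop is anchored at the contig edge (a gene may continue off
#' the fragment), while the run downstream of the last stop still requires
#' a start codon.  Codons containing IUPAC ambiguity codes never count as
#' stops.
#'
#' Coordinates are 0-based half-open on the forward strand; for
#' minus-strand ORFs `start`/`end` still refer to forward-strand positions.
#' `n_reassigned_in_frame` counts in-frame occurrences of the code's
#' reassigned codon (TAG for table 15, TGA for table 4) inside the ORF,
#' excluding a terminal stop; it is 0 under table 11.
#'
#' @param seq DNA string (a contig).
#' @param code A [genetic_code()].
#' @param min_len_nt Minimum ORF length in nucleotides, including the
#'   terminal stop codon; must be a positive multiple of 3 (default 90).
#' @param contig_id Identifier copied into the output.
#' @return A data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame` (0..2 on the coding strand), `complete`,
#'   `n_reassigned_in_frame`, `code_id`, ordered by `start`, `end`, strand.
#' @examples
#' find_orfs("ATGAAATAGAAATAA", genetic_code(11), min_len_nt = 9)
#' @export
find_orfs <- function(seq, code, min_len_nt = 90L, contig_id = "contig") {
  stopifnot(inherits(code, "genetic_code"))
  if (min_len_nt < 3L || min_len_nt %% 3L != 0L) {
    stop("min_len_nt must be a positive multiple of 3", call. = FALSE)
  }
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L) return(.empty_orf_frame())
  .check_dna(seq)

  fwd <- .scan_strand(seq, code, min_len_nt)
  rev <- .scan_strand(reverse_complement(seq), code, min_len_nt)
  if (nrow(rev) > 0L) {
    s <- rev$start
    rev$start <- L - rev$end
    rev$end <- L - s
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0L) return(.empty_orf_frame())
  out$contig_id <- contig_id
  out$code_id <- code$table_id
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("contig_id", "start", "end", "strand", "frame", "complete",
          "n_reassigned_in_frame", "code_id")]
}

# One strand; coordinates relative to the scanned string.
.scan_strand <- function(s, code, min_len_nt) {
  L <- nchar(s)
  res <- vector("list", 3L)
  re_codon <- if (is.null(code$reassignment)) NA_character_ else
    code$reassignment$codon
  for (f in 0:2) {
    starts_nt <- seq.int(f + 1L, by = 3L, length.out = (L - f) %/% 3L)
    if (length(starts_nt) == 0L) next
    codons <- substring(s, starts_nt, starts_nt + 2L)
    is_stop <- codons %in% code$stop_set
    is_start <- codons %in% code$start_set
    n <- length(codons)
    stop_idx <- which(is_stop)
    seg_begin <- c(1L, stop_idx + 1L)
    seg_stop <- c(stop_idx, NA_integer_)  # NA: trailing stop-free run
    rows <- list()
    for (k in seq_along(seg_begin)) {
      b <- seg_begin[k]
      t <- seg_stop[k]
      leading <- (b == 1L)
      if (!is.na(t)) {
        if (t < b) next  # empty interval (consecutive stops)
        first_start <- b - 1L + match(TRUE, is_start[b:t])
        if (leading) {
          from <- 1L
          complete <- isTRUE(first_start == 1L)
        } else {
          if (is.na(first_start) || first_start == t) next
          from <- first_start
          complete <- TRUE
        }
        to <- t
        with_stop <- TRUE
      } else {
        if (b > n) next
        first_start <- b - 1L + match(TRUE, is_start[b:n])
        if (leading) {
          from <- 1L
        } else {
          if (is.na(first_start)) next
          from <- first_start
        }
        to <- n
        complete <- FALSE
        with_stop <- FALSE
      }
      start0 <- starts_nt[from] - 1L
      end0 <- starts_nt[to] + 2L
      if (end0 - start0 < min_len_nt) next
      internal <- if (with_stop) seq_len(to - from) + from - 1L else from:to
      n_re <- if (is.na(re_codon)) 0L else
        sum(codons[internal] == re_codon)
      rows[[length(rows) + 1L]] <- list(
        start = start0, end = end0, frame = f,
        complete = complete, n_reassigned_in_frame = as.integer(n_re))
    }
    if (length(rows) > 0L) {
      res[[f + 1L]] <- data.frame(
        start = vapply(rows, `[[`, integer(1), "start"),
        end = vapply(rows, `[[`, integer(1), "end"),
        strand = "+", frame = f,
        complete = vapply(rows, `[[`, logical(1), "complete"),
        n_reassigned_in_frame =
          vapply(rows, `[[`, integer(1), "n_reassigned_in_frame"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      complete = logical(0),
                      n_reassigned_in_frame = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}
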