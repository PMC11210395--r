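# Internal helpers shared across modules.

IUPAC_DNA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")

# 0-based base codes for the unambiguous alphabet; NA for ambiguity codes.
.base_code <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 0L
  v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L
  v[utf8ToInt("T")] <- 3L
  v
})

#' @noRd
.encode_seq <- function(seq) {
  ints <- utf8ToInt(seq)
  if (length(ints) == 0L) return(integer(0))
  .base_code[ints]
}

.check_dna <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% IUPAC_DNA))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(TRUE)
}

# Round half away from zero at `digits` decimals; base round() ties to even,
# which would print 72.95 as 72.9 rather than 73.0.
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Proportion as a percentage at one decimal
#'
#' `100 * k / n` rounded half-up to one decimal place (the reporting
#' precision used throughout); 0 when `n` is 0.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return Percentage at one decimal.
#' @examples
#' proportion_pct(375, 715)  # 52.4
#' @export
proportion_pct <- function(k, n) {
  if (n <= 0) return(0)
  round_half_up(100 * k / n, 1L)
}

.empty_orf_frame <- function() {
  data.frame(
    contig_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), frame = integer(0), complete = logical(0),
    n_reassigned_in_frame = integer(0), code_id = character(0),
    stringsAsFactors = FALSE
  )
}
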