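#' Candidate genetic codes
#'
#' The package works with the standard prokaryotic code and the two
#' stop-codon reassignments documented in phages: NCBI translation table 11
#' (stops TAA, TAG, TGA), table 4 (TGA read as tryptophan, W) and table 15
#' (TAG read as glutamine, Q).  A generic variant `"tag-unknown"` models
#' lineages where TAG is repurposed to an amino acid that has not been
#' identified; it translates TAG as `X` and is not part of the default
#' candidate set.
#'
#' @param table_id One of `11`, `4`, `15` (integers or their character
#'   forms) or `"tag-unknown"`.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over all 64 codons,
#'   stops encoded as `"*"`), `stop_set`, `start_set` and `reassignment`
#'   (`NULL` for table 11, otherwise `list(codon=, aa=)`).
#'
#' @examples
#' genetic_code(15)$stop_set     # TAA, TGA -- TAG is glutamine
#' translate_codon("TGA", genetic_code(4))
#' @export
genetic_code <- function(table_id) {
  id <- as.character(table_id)
  if (!id %in% c("11", "4", "15", "tag-unknown")) {
    stop(sprintf("unsupported genetic code '%s' (supported: 11, 4, 15, tag-unknown)",
                 id), call. = FALSE)
  }
  codon_to_aa <- .table11_map()
  reassignment <- NULL
  if (id == "15") {
    codon_to_aa[["TAG"]] <- "Q"
    reassignment <- list(codon = "TAG", aa = "Q")
  } else if (id == "4") {
    codon_to_aa[["TGA"]] <- "W"
    reassignment <- list(codon = "TGA", aa = "W")
  } else if (id == "tag-unknown") {
    codon_to_aa[["TAG"]] <- "X"
    reassignment <- list(codon = "TAG", aa = "X")
  }
  structure(
    list(
      table_id = id,
      codon_to_aa = codon_to_aa,
      stop_set = names(codon_to_aa)[codon_to_aa == "*"],
      start_set = c("ATG", "GTG", "TTG"),
      reassignment = reassignment
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code table %s>\n", x$table_id))
  cat("  stops : ", paste(x$stop_set, collapse = ", "), "\n", sep = "")
  cat("  starts: ", paste(x$start_set, collapse = ", "), "\n", sep = "")
  if (!is.null(x$reassignment)) {
    cat(sprintf("  reassigned: %s -> %s\n",
                x$reassignment$codon, x$reassignment$aa))
  }
  invisible(x)
}

# Standard bacterial/archaeal/plastid code (table 11), DNA alphabet.
.table11_map <- function() {
  bases <- c("T", "C", "A", "G")
  # NCBI amino-acid string for tables 1/11, TCAG codon order.
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  codons <- character(64)
  i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
}

#' Translate a single codon
#'
#' Codons containing IUPAC ambiguity codes translate to `X` and are never
#' treated as stops, so draft-genome ambiguity cannot truncate a gene.
#'
#' @param codon A 3-mer DNA string (case-insensitive).
#' @param code A [genetic_code()].
#' @return One-letter amino acid, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon, code) {
  stopifnot(inherits(code, "genetic_code"))
  codon <- toupper(codon)
  if (nchar(codon) != 3L) {
    stop("codon must be a 3-mer", call. = FALSE)
  }
  .check_dna(codon, "codon")
  aa <- code$codon_to_aa[codon]
  if (is.na(aa)) "X" else unname(aa)
}

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet; an empty string maps to itself.
#'
#' @param seq DNA string.
#' @return The reverse complement, preserving case as uppercase.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(seq)
  .check_dna(seq)
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}
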