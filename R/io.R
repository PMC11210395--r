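#' Read a FASTA file
#'
#' Parses multi-record FASTA, tolerating mixed case, CRLF line endings and
#' blank lines.  Sequences are uppercased.  Duplicate record ids, empty
#' records and non-IUPAC characters are format errors reported with line
#' numbers.
#'
#' @param path Path to a FASTA file.
#' @return Data.frame with columns `id` (first whitespace-delimited header
#'   token), `description` (remainder of the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[which(nzchar(lines))[1]]) {
    stop(sprintf("%s: line %d: expected '>' header", path,
                 which(nzchar(lines))[1]), call. = FALSE)
  }
  idx <- which(hdr)
  ids <- character(length(idx))
  desc <- character(length(idx))
  seqs <- character(length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (k in seq_along(idx)) {
    header <- sub("^>", "", lines[idx[k]])
    tok <- strsplit(trimws(header), "\\s+")[[1]]
    if (length(tok) == 0L || !nzchar(tok[1])) {
      stop(sprintf("%s: line %d: empty record id", path, idx[k]),
           call. = FALSE)
    }
    ids[k] <- tok[1]
    desc[k] <- trimws(sub("^\\S+\\s*", "", trimws(header)))
    body <- if (idx[k] + 1L > bounds[k + 1L] - 1L) character(0) else
      lines[seq.int(idx[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body)]
    seqs[k] <- toupper(paste(body, collapse = ""))
    if (!nzchar(seqs[k])) {
      stop(sprintf("%s: line %d: record '%s' has an empty sequence",
                   path, idx[k], ids[k]), call. = FALSE)
    }
    chars <- strsplit(seqs[k], "")[[1]]
    bad <- which(!(chars %in% IUPAC_DNA))
    if (length(bad) > 0L) {
      # locate the offending line for the report
      off <- bad[1]
      line_no <- idx[k]
      for (b in seq.int(idx[k] + 1L, bounds[k + 1L] - 1L)) {
        n <- nchar(lines[b])
        if (off <= n) { line_no <- b; break }
        off <- off - n
      }
      stop(sprintf("%s: line %d: invalid sequence character '%s'",
                   path, line_no, chars[bad[1]]), call. = FALSE)
    }
  }
  dup <- anyDuplicated(ids)
  if (dup > 0L) {
    stop(sprintf("%s: line %d: duplicate record id '%s'", path,
                 idx[dup], ids[dup]), call. = FALSE)
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' Uppercase sequence, 60-column wrapping.
#'
#' @param records Data.frame with `id`, optional `description`, and
#'   `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    d <- if ("description" %in% names(records) &&
             nzchar(records$description[k]))
      paste0(" ", records$description[k]) else ""
    writeLines(paste0(">", records$id[k], d), con)
    s <- toupper(records$sequence[k])
    starts <- seq.int(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read CDS/tRNA features from GFF3
#'
#' File coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default CDS and tRNA).
#' @return Data.frame with `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `transl_table` (NA when absent), `id`.
#' @export
read_gff3 <- function(path, types = c("CDS", "tRNA")) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop(sprintf("%s: malformed GFF3: %s", path,
                                conditionMessage(e)), call. = FALSE))
  df <- as.data.frame(gr)
  df <- df[df$type %in% types, , drop = FALSE]
  tt <- if ("transl_table" %in% names(df))
    as.character(df$transl_table) else NA_character_
  id <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  out <- data.frame(
    contig_id = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                    as.character(df$strand), "+"),
    type = as.character(df$type),
    transl_table = tt,
    id = id,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write features to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention; the genetic code is recorded as a
#' `transl_table` attribute on each CDS.
#'
#' @param features Data.frame with `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, and optional `transl_table`, `id`,
#'   `score_bits` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) > 0L && any(features$end <= features$start)) {
    stop("features must satisfy start < end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$type
  if ("id" %in% names(features)) {
    S4Vectors::mcols(gr)$ID <- features$id
  }
  if ("transl_table" %in% names(features)) {
    S4Vectors::mcols(gr)$transl_table <- features$transl_table
  }
  if ("score_bits" %in% names(features)) {
    S4Vectors::mcols(gr)$score <- round(features$score_bits, 3)
  }
  S4Vectors::mcols(gr)$source <- "phagecode"
  S4Vectors::mcols(gr)$phase <-
    ifelse(features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert gene calls to a GFF3 feature frame
#'
#' @param calls A [call_genes()] result.
#' @return Data.frame suitable for [write_gff3()].
#' @export
calls_to_features <- function(calls) {
  data.frame(
    contig_id = calls$contig_id, start = calls$start, end = calls$end,
    strand = calls$strand, type = "CDS", transl_table = calls$code_id,
    id = sprintf("%s_cds_%04d", calls$contig_id, seq_len(nrow(calls))),
    score_bits = calls$score_bits, stringsAsFactors = FALSE)
}
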