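#' Configuration for the synthetic phage-genome generator
#'
#' Defaults mirror cultured-phage statistics: median gene length 550 nt
#' (lognormal, sigma 0.45), short geometric intergenic gaps (mean 60 nt)
#' giving ~90% true coding density, ~30 kb genomes at the default gene
#' count, both strands, GC 45%, and a 0.3 probability that each eligible
#' amino-acid position (Gln for table 15, Trp for table 4) uses the
#' reassigned stop codon.
#'
#' @param seed Integer RNG seed; the whole genome is a deterministic
#'   function of the config.
#' @param n_genes Number of genes (default 45, ~30 kb).
#' @param gene_len_median_nt,gene_len_sigma Lognormal gene-length
#'   parameters (median >= 120 nt).
#' @param intergenic_mean_nt Mean geometric intergenic gap (nt).
#' @param gc GC-content target in (0, 1).
#' @param code_id True genetic code of the genome (11, 4 or 15).
#' @param q Probability that an eligible position uses the reassigned
#'   codon (ignored for table 11).
#' @param minus_strand_fraction Probability a gene lies on the minus
#'   strand.
#' @param embed_trna Optional anticodon (e.g. `"CTA"`); when set, a
#'   canonical cloverleaf cassette is inserted into an intergenic gap.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_genes = 45L,
                             gene_len_median_nt = 550, gene_len_sigma = 0.45,
                             intergenic_mean_nt = 60, gc = 0.45,
                             code_id = 11, q = 0.3,
                             minus_strand_fraction = 0.3,
                             embed_trna = NULL) {
  stopifnot(n_genes >= 1L, gene_len_median_nt >= 120, gene_len_sigma > 0,
            intergenic_mean_nt >= 0, gc > 0, gc < 1, q >= 0, q <= 1,
            minus_strand_fraction >= 0, minus_strand_fraction <= 1)
  if (n_genes * gene_len_median_nt > 5e6) {
    stop("infeasible config: genome would exceed 5 Mb", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len_median_nt = gene_len_median_nt,
                 gene_len_sigma = gene_len_sigma,
                 intergenic_mean_nt = intergenic_mean_nt, gc = gc,
                 code_id = as.character(code_id), q = q,
                 minus_strand_fraction = minus_strand_fraction,
                 embed_trna = embed_trna),
            class = "generator_config")
}

# Codon sampling weights: base-composition prior times a fixed per-codon
# usage bias (the bias is what gives the hexamer model its signal), with
# glutamine/tryptophan codons boosted so reassignment-eligible positions
# are plentiful, then exponentially tilted so the expected GC of coding
# sequence matches the target.
.codon_weights <- function(code, gc) {
  map <- code$codon_to_aa
  codons <- names(map)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  comp <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    prod(base_p[b])
  }
  p0 <- vapply(codons, comp, numeric(1))
  mult <- rep(c(4, 1, 0.25), length.out = 64)
  names(mult) <- codons
  mult[c("CAA", "CAG", "TGG")] <- 6
  w <- p0 * mult
  sense <- !(codons %in% code$stop_set)
  if (!is.null(code$reassignment)) {
    sense <- sense & codons != code$reassignment$codon
  }
  w[!sense] <- 0
  gcount <- vapply(codons, function(codon)
    sum(strsplit(codon, "")[[1]] %in% c("G", "C")), numeric(1))
  target <- 3 * gc
  f <- function(logt) {
    wt <- w * exp(logt * gcount)
    sum(wt * gcount) / sum(wt) - target
  }
  logt <- stats::uniroot(f, c(-5, 5))$root
  wt <- w * exp(logt * gcount)
  wt / sum(wt)
}

.random_bases <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a phage-like genome with known ground truth
#'
#' Genes are drawn from the configured length distribution, built codon
#' by codon from a GC-tilted biased usage table under the true code,
#' started with ATG/GTG/TTG and ended with a stop codon of the true code.
#' Eligible positions (Gln codons for table 15, Trp codons for table 4)
#' are swapped to the reassigned stop codon with probability `q`, so a
#' table-11 annotation of a reassigned genome truncates genes at the
#' first swapped codon.  Genes are laid out left to right with geometric
#' intergenic gaps and placed on the minus strand with the configured
#' probability.
#'
#' @param config A [generator_config()].
#' @return Object of class `truth_set`: list with `seq`, `contig_id`,
#'   `code_id`, `genes` (data.frame: `gene_id`, `start`, `end` 0-based
#'   half-open forward-strand, `strand`, `n_reassigned`), `trna`
#'   (`NULL` or `list(start, end, anticodon)`) and `config`.
#' @examples
#' ts <- generate_genome(generator_config(seed = 1, n_genes = 5))
#' ts$genes
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  code <- genetic_code(config$code_id)
  with_seed(config$seed, {
    cw <- .codon_weights(code, config$gc)
    codon_names <- names(cw)
    eligible_aa <- if (is.null(code$reassignment)) NA_character_ else
      code$reassignment$aa
    eligible_codons <- if (is.na(eligible_aa)) character(0) else
      names(code$codon_to_aa)[code$codon_to_aa == eligible_aa &
                                names(code$codon_to_aa) !=
                                  code$reassignment$codon]

    lens <- stats::rlnorm(config$n_genes,
                          meanlog = log(config$gene_len_median_nt),
                          sdlog = config$gene_len_sigma)
    lens <- pmin(pmax(round(lens / 3) * 3, 120), 6000)
    gaps <- stats::rgeom(config$n_genes + 1L,
                         prob = 1 / (config$intergenic_mean_nt + 1))
    strands <- ifelse(stats::runif(config$n_genes) <
                        config$minus_strand_fraction, "-", "+")

    pieces <- character(2L * config$n_genes + 1L)
    genes <- vector("list", config$n_genes)
    pos <- 0L
    pieces[1L] <- .random_bases(gaps[1L], config$gc)
    pos <- pos + gaps[1L]
    for (i in seq_len(config$n_genes)) {
      n_codons <- lens[i] / 3L
      start_codon <- sample(code$start_set, 1L,
                            prob = c(0.8, 0.15, 0.05))
      stop_codon <- sample(code$stop_set, 1L)
      body <- sample(codon_names, n_codons - 2L, replace = TRUE, prob = cw)
      n_re <- 0L
      if (length(eligible_codons) > 0L && config$q > 0) {
        elig <- which(body %in% eligible_codons)
        swap <- elig[stats::runif(length(elig)) < config$q]
        body[swap] <- code$reassignment$codon
        n_re <- length(swap)
      }
      gene_seq <- paste(c(start_codon, body, stop_codon), collapse = "")
      if (strands[i] == "-") gene_seq <- reverse_complement(gene_seq)
      pieces[2L * i] <- gene_seq
      genes[[i]] <- data.frame(
        gene_id = sprintf("gene_%03d", i),
        start = pos, end = pos + lens[i], strand = strands[i],
        n_reassigned = n_re, stringsAsFactors = FALSE)
      pos <- pos + lens[i]
      pieces[2L * i + 1L] <- .random_bases(gaps[i + 1L], config$gc)
      pos <- pos + gaps[i + 1L]
    }
    truth <- structure(list(
      seq = paste(pieces, collapse = ""),
      contig_id = sprintf("synth_seed%d", config$seed),
      code_id = config$code_id,
      genes = do.call(rbind, genes),
      trna = NULL,
      config = config
    ), class = "truth_set")
    if (!is.null(config$embed_trna)) {
      truth <- embed_trna(truth, config$embed_trna)
    }
    truth
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set %s: %d nt, %d genes, code %s%s>\n",
              x$contig_id, nchar(x$seq), nrow(x$genes), x$code_id,
              if (is.null(x$trna)) "" else
                sprintf(", tRNA(%s) at %d", x$trna$anticodon,
                        x$trna$start)))
  invisible(x)
}

#' Build a canonical 76-nt cloverleaf tRNA cassette
#'
#' The cassette satisfies the detector's stem rules perfectly (structure
#' score 21 over the 72-nt folded region, plus an ACCA 3' tail) and
#' carries the given anticodon at the canonical position.
#'
#' @param anticodon 3-mer DNA anticodon (5'->3').
#' @return 76-nt DNA string.
#' @export
build_trna_cassette <- function(anticodon) {
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L)
  .check_dna(anticodon, "anticodon")
  paste0(
    "GCGGATT",            # acceptor 5' (1-7)
    "TA",                 # 8-9
    "GCTC",               # D stem 5' (10-13)
    "AGTTGGTA",           # D loop (14-21)
    "GAGC",               # D stem 3' (22-25)
    "A",                  # 26
    "CTGGG",              # anticodon stem 5' (27-31)
    "CT", anticodon, "AA",# anticodon loop (32-38), anticodon at 34-36
    "CCCAG",              # anticodon stem 3' (39-43)
    "AGGTC",              # variable loop (44-48)
    "GGTTC",              # T stem 5' (49-53)
    "TTCGAAT",            # T loop (54-60)
    "GAACC",              # T stem 3' (61-65)
    "AATCCGC",            # acceptor 3' (66-72)
    "ACCA"                # discriminator + CCA tail (73-76)
  )
}

#' Embed a suppressor tRNA cassette into a truth genome
#'
#' Inserts a [build_trna_cassette()] sequence into an intergenic gap and
#' updates the ground truth (gene intervals downstream shift by 76 nt).
#'
#' @param truth A [generate_genome()] result.
#' @param anticodon 3-mer DNA anticodon.
#' @param position Optional 0-based insertion offset; must lie in an
#'   intergenic gap with 76 nt of room.  Default: 10 nt into the first
#'   gap at least 96 nt wide.
#' @return The updated `truth_set`.
#' @export
embed_trna <- function(truth, anticodon, position = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  cassette <- build_trna_cassette(anticodon)
  L <- nchar(truth$seq)
  g <- truth$genes[order(truth$genes$start), , drop = FALSE]
  gap_start <- c(0L, g$end)
  gap_end <- c(g$start, L)
  widths <- gap_end - gap_start
  if (is.null(position)) {
    k <- which(widths >= 96L)[1]
    if (is.na(k)) k <- which.max(widths)
    position <- if (widths[k] >= 76L) {
      gap_start[k] + min(10L, (widths[k] - 76L) %/% 2L)
    } else {
      L  # no interior gap wide enough: append past the last gene
    }
  } else {
    ok <- any(position >= gap_start & position <= gap_end)
    if (!ok) stop("position does not lie in an intergenic gap",
                  call. = FALSE)
  }
  truth$seq <- paste0(substr(truth$seq, 1L, position), cassette,
                      substr(truth$seq, position + 1L, L))
  shift <- truth$genes$start >= position
  truth$genes$start[shift] <- truth$genes$start[shift] + nchar(cassette)
  truth$genes$end[shift] <- truth$genes$end[shift] + nchar(cassette)
  truth$trna <- list(start = position, end = position + nchar(cassette),
                     anticodon = anticodon)
  truth
}

#' Write a truth set to FASTA + GFF3 + JSON
#'
#' @param truth A `truth_set`.
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.gff3` and `<prefix>.truth.json`.
#' @return Invisibly, the three paths.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "truth_set"))
  paths <- paste0(prefix, c(".fasta", ".gff3", ".truth.json"))
  write_fasta(data.frame(id = truth$contig_id,
                         description = sprintf("synthetic code=%s",
                                               truth$code_id),
                         sequence = truth$seq, stringsAsFactors = FALSE),
              paths[1])
  feat <- data.frame(
    contig_id = truth$contig_id, start = truth$genes$start,
    end = truth$genes$end, strand = truth$genes$strand, type = "CDS",
    transl_table = truth$code_id, id = truth$genes$gene_id,
    stringsAsFactors = FALSE)
  if (!is.null(truth$trna)) {
    feat <- rbind(feat, data.frame(
      contig_id = truth$contig_id, start = truth$trna$start,
      end = truth$trna$end, strand = "+", type = "tRNA",
      transl_table = NA_character_,
      id = sprintf("trna_%s", truth$trna$anticodon),
      stringsAsFactors = FALSE))
  }
  write_gff3(feat, paths[2])
  cfg <- truth$config
  cfg$embed_trna <- if (is.null(cfg$embed_trna)) NA else cfg$embed_trna
  jsonlite::write_json(
    list(config = unclass(cfg), contig_id = truth$contig_id,
         code_id = truth$code_id, genome_len = nchar(truth$seq),
         n_genes = nrow(truth$genes)),
    paths[3], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
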