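#' Coding capacity of an annotation
#'
#' Percentage of genome nucleotides covered by the union of gene
#' intervals.  Overlapping genes are counted once and strand is ignored,
#' so the result cannot exceed 100 and the ~90% typical of cultured phages
#' is directly comparable.
#'
#' @param intervals Data.frame (or matrix) with `start`/`end` columns,
#'   0-based half-open; may be empty.
#' @param genome_len Genome length in nucleotides (> 0).
#' @return Percentage in \[0, 100\] (not rounded).
#' @examples
#' coding_capacity(data.frame(start = c(0, 400), end = c(600, 800)), 1000)
#' @export
coding_capacity <- function(intervals, genome_len) {
  stopifnot(genome_len > 0)
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) return(0)
  s <- as.numeric(intervals$start)
  e <- as.numeric(intervals$end)
  if (any(s < 0) || any(e > genome_len) || any(e <= s)) {
    stop("intervals must satisfy 0 <= start < end <= genome_len",
         call. = FALSE)
  }
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  covered <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  covered <- covered + (cur_e - cur_s)
  100 * covered / genome_len
}

#' Median gene length
#'
#' @param intervals Data.frame with `start`/`end` (0-based half-open).
#' @return Median of `end - start` in nucleotides; even counts use the
#'   midpoint mean; an empty annotation returns 0 with a warning.
#' @export
median_gene_length <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) {
    warning("no genes: median gene length reported as 0", call. = FALSE)
    return(0)
  }
  stats::median(as.numeric(intervals$end) - as.numeric(intervals$start))
}

#' Median of per-genome medians
#'
#' Dataset-level summary used for gene length: each genome contributes its
#' own median, and the dataset value is the median of those.
#'
#' @param per_genome_medians Numeric vector, one value per genome.
#' @return The median of the per-genome medians.
#' @export
median_of_genome_medians <- function(per_genome_medians) {
  stopifnot(length(per_genome_medians) >= 1L)
  stats::median(as.numeric(per_genome_medians))
}

#' Fraction of hypothetical (unannotated) proteins
#'
#' @param labels Character vector of per-gene function labels.
#' @param hypothetical_label The label denoting an unannotated product
#'   (default `"hypothetical"`).
#' @return Percentage at one decimal (half-up).
#' @export
hypothetical_fraction <- function(labels,
                                  hypothetical_label = "hypothetical") {
  if (length(labels) == 0L) return(0)
  proportion_pct(sum(labels == hypothetical_label), length(labels))
}

#' Percent increase between two values
#'
#' `100 * (after - before) / before`, rounded half-up to one decimal, the
#' precision annotation-improvement percentages are reported at.
#'
#' @param before,after Positive baseline value and new value.
#' @return Percentage at one decimal.
#' @examples
#' percent_increase(350, 518)  # 48.0
#' @export
percent_increase <- function(before, after) {
  if (before <= 0) stop("before must be > 0", call. = FALSE)
  round_half_up(100 * (after - before) / before, 1L)
}

#' Paired two-sided t test
#'
#' Tests the mean of the paired differences `b - a` against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors, paired by position.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  n <- length(a)
  d <- b - a
  if (n < 2L || isTRUE(all.equal(stats::var(d), 0)) ||
      stats::var(d) == 0) {
    stop("degenerate input: need n >= 2 and non-constant differences",
         call. = FALSE)
  }
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are returned in the
#' input order and never drop below the raw p values.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-genome annotation metrics
#'
#' @param intervals Gene intervals (0-based half-open `start`/`end`).
#' @param genome_len Genome length in nt.
#' @param labels Optional per-gene function labels for the hypothetical
#'   fraction.
#' @param genome_id Identifier.
#' @return One-row data.frame with `genome_id`, `n_genes`,
#'   `median_gene_len_nt`, `coding_capacity_pct`, `genes_per_kb` and
#'   `hypothetical_fraction_pct` (NA without labels).
#' @export
genome_metrics <- function(intervals, genome_len, labels = NULL,
                           genome_id = "genome") {
  intervals <- as.data.frame(intervals)
  n <- nrow(intervals)
  data.frame(
    genome_id = genome_id,
    n_genes = n,
    median_gene_len_nt = suppressWarnings(median_gene_length(intervals)),
    coding_capacity_pct = if (n > 0L)
      coding_capacity(intervals, genome_len) else 0,
    genes_per_kb = n / (genome_len / 1000),
    hypothetical_fraction_pct = if (is.null(labels)) NA_real_
      else hypothetical_fraction(labels),
    stringsAsFactors = FALSE
  )
}

#' Compare two annotation strategies across paired genomes
#'
#' Computes per-genome metrics under each strategy, then a paired t test
#' per metric (differences taken as B minus A) and a Benjamini-Hochberg
#' adjustment across the family of metric tests.  Genomes must be the
#' same, in the same order, under both strategies.  Degenerate metrics
#' (identical values under both strategies) are reported with NA test
#' columns.
#'
#' @param annotations_a,annotations_b Named lists of gene-interval
#'   data.frames (0-based half-open), one entry per genome.
#' @param genome_lens Named numeric vector of genome lengths.
#' @param labels_a,labels_b Optional named lists of per-gene label
#'   vectors.
#' @return Object of class `strategy_comparison`: a data.frame with one
#'   row per metric (`metric`, `mean_a`, `mean_b`, `mean_diff`,
#'   `t_statistic`, `df`, `p_value_raw`, `p_value_bh`), with the
#'   per-genome metric tables attached as attributes `metrics_a` and
#'   `metrics_b`.
#' @export
compare_strategies <- function(annotations_a, annotations_b, genome_lens,
                               labels_a = NULL, labels_b = NULL) {
  ids <- names(annotations_a)
  if (is.null(ids) || !identical(ids, names(annotations_b))) {
    stop("strategies must cover identical genome sets (same names, same order)",
         call. = FALSE)
  }
  per_genome <- function(ann, labels) {
    do.call(rbind, lapply(ids, function(id) {
      genome_metrics(ann[[id]], genome_lens[[id]],
                     labels = if (is.null(labels)) NULL else labels[[id]],
                     genome_id = id)
    }))
  }
  ma <- per_genome(annotations_a, labels_a)
  mb <- per_genome(annotations_b, labels_b)
  metrics <- c("median_gene_len_nt", "coding_capacity_pct", "genes_per_kb")
  if (!is.null(labels_a) && !is.null(labels_b)) {
    metrics <- c(metrics, "hypothetical_fraction_pct")
  }
  rows <- lapply(metrics, function(m) {
    va <- ma[[m]]; vb <- mb[[m]]
    res <- tryCatch(paired_t_test(va, vb), error = function(e) NULL)
    data.frame(metric = m, mean_a = mean(va), mean_b = mean(vb),
               mean_diff = mean(vb - va),
               t_statistic = if (is.null(res)) NA_real_ else res$t,
               df = if (is.null(res)) NA_real_ else res$df,
               p_value_raw = if (is.null(res)) NA_real_ else res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value_raw)
  out$p_value_bh <- NA_real_
  if (any(ok)) out$p_value_bh[ok] <- bh_adjust(out$p_value_raw[ok])
  attr(out, "metrics_a") <- ma
  attr(out, "metrics_b") <- mb
  class(out) <- c("strategy_comparison", "data.frame")
  out
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison over %d genomes>\n",
              nrow(attr(x, "metrics_a"))))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Box/strip plot of a paired metric comparison
#'
#' Simple base-graphics rendering of the paired per-genome values under
#' the two strategies, with grey segments joining each genome's pair.
#'
#' @param x A [compare_strategies()] result.
#' @param metric Which metric column to draw.
#' @param names Labels for the two strategies.
#' @param ... Passed to [boxplot()].
#' @export
plot_strategy_comparison <- function(x, metric = "median_gene_len_nt",
                                     names = c("A", "B"), ...) {
  ma <- attr(x, "metrics_a")[[metric]]
  mb <- attr(x, "metrics_b")[[metric]]
  graphics::boxplot(list(ma, mb), names = names, ylab = metric, ...)
  graphics::segments(1, ma, 2, mb, col = grDevices::grey(0.6))
  graphics::points(rep(1, length(ma)), ma, pch = 16)
  graphics::points(rep(2, length(mb)), mb, pch = 16)
  invisible(x)
}
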