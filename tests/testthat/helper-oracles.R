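# Independent brute-force oracles used to validate the fast
# implementations.  These deliberately use naive loops and simple data
# structures; they share no code with the package internals.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Naive six-frame ORF scanner implementing the documented contract:
# one ORF per stop-to-stop interval (first start to terminal stop),
# leading stop-free run anchored at the contig edge, trailing run
# requiring a start codon; ORFs shorter than min_len dropped.
brute_orfs <- function(seq, code, min_len) {
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (f in 0:2) {
      n_codons <- (L - f) %/% 3
      if (n_codons == 0) next
      codons <- sapply(seq_len(n_codons), function(i)
        substr(s, f + 3 * i - 2, f + 3 * i))
      is_stop <- codons %in% code$stop_set
      is_start <- codons %in% code$start_set
      seg_first <- 1
      emit <- function(from, to, complete) {
        start0 <- f + 3 * (from - 1)
        end0 <- f + 3 * to
        if (end0 - start0 < min_len) return(NULL)
        if (strand == "-") {
          tmp <- start0
          start0 <- L - end0
          end0 <- L - tmp
        }
        list(start = start0, end = end0, strand = strand,
             complete = complete)
      }
      for (i in seq_len(n_codons)) {
        if (is_stop[i]) {
          span <- seg_first:i
          leading <- seg_first == 1
          first_start <- span[which(is_start[span])[1]]
          if (leading) {
            out <- c(out, list(emit(1, i, isTRUE(is_start[1]))))
          } else if (!is.na(first_start) && first_start < i) {
            out <- c(out, list(emit(first_start, i, TRUE)))
          }
          seg_first <- i + 1
        }
      }
      if (seg_first <= n_codons) {  # trailing stop-free run
        span <- seg_first:n_codons
        leading <- seg_first == 1
        first_start <- span[which(is_start[span])[1]]
        if (leading) {
          out <- c(out, list(emit(1, n_codons, FALSE)))
        } else if (!is.na(first_start)) {
          out <- c(out, list(emit(first_start, n_codons, FALSE)))
        }
      }
    }
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), complete = logical(0)))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df[order(df$start, df$end, df$strand), ]
}

# Per-base boolean-mask coding capacity.
mask_capacity <- function(intervals, genome_len) {
  mask <- logical(genome_len)
  for (i in seq_len(nrow(intervals))) {
    mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  100 * sum(mask) / genome_len
}

# Step-up BH from first principles.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# Exhaustive best-score subset under the pairwise overlap allowance.
best_subset_score <- function(df, max_overlap) {
  n <- nrow(df)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) {
        if (i < j) {
          ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
          if (ov > max_overlap) { ok <- FALSE; break }
        }
      }
    }
    if (ok) best <- max(best, sum(df$score_bits[idx]))
  }
  best
}

# Translate a coding-strand gene sequence with a plain codon loop.
translate_cds <- function(cds, code) {
  n <- nchar(cds) %/% 3
  sapply(seq_len(n), function(i)
    translate_codon(substr(cds, 3 * i - 2, 3 * i), code))
}

# In-frame hexamer score of a coding-strand sequence under a model,
# recomputed from first principles (no per-gene penalty).
hexscore2 <- function(model, cds) {
  v <- match(strsplit(cds, "")[[1]], c("A", "C", "G", "T")) - 1
  st <- seq(1, length(v) - 5, 3)
  idx <- v[st] * 1024 + v[st + 1] * 256 + v[st + 2] * 64 +
    v[st + 3] * 16 + v[st + 4] * 4 + v[st + 5] + 1
  sum(model$hexamer_logodds[idx])
}

gene_cds <- function(truth, i) {
  g <- truth$genes[i, ]
  s <- substr(truth$seq, g$start + 1, g$end)
  if (g$strand == "-") s <- reverse_complement(s) else s
}
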