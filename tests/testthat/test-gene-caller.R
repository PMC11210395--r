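test_that("short or ORF-free input degrades to a uniform model", {
  expect_warning(m <- train_coding_model(random_dna(500), genetic_code(11)),
                 "uniform")
  expect_true(m$uniform)
  expect_true(all(m$hexamer_logodds == 0))
  # TTAAG repeats put a stop within 5 codons in all six frames
  seq <- strrep("TTAAG", 450)
  expect_warning(m2 <- train_coding_model(seq, genetic_code(11)),
                 "uniform")
  expect_true(m2$uniform)
})

test_that("training is deterministic and scores are additive in hexamers", {
  ts <- generate_genome(generator_config(seed = 3, n_genes = 20))
  m1 <- train_coding_model(ts$seq, genetic_code(11))
  m2 <- train_coding_model(ts$seq, genetic_code(11))
  expect_identical(m1, m2)

  orfs <- find_orfs(ts$seq, genetic_code(11))
  scored <- score_orfs(orfs, ts$seq, m1, per_gene_penalty_bits = 0)
  # additivity: score of an ORF equals the sum over its own hexamer walk
  i <- which.max(scored$end - scored$start)
  cds <- substr(ts$seq, scored$start[i] + 1, scored$end[i])
  if (scored$strand[i] == "-") cds <- reverse_complement(cds)
  if (scored$complete[i]) cds <- substr(cds, 1, nchar(cds) - 3)
  hx <- substring(cds, seq(1, nchar(cds) - 5, 3), seq(6, nchar(cds), 3))
  codes <- sapply(hx, function(h) {
    v <- match(strsplit(h, "")[[1]], c("A", "C", "G", "T")) - 1
    sum(v * 4^(5:0)) + 1
  })
  expect_equal(scored$score_bits[i], sum(m1$hexamer_logodds[codes]))
})

test_that("uniform model scores every ORF at minus the gene penalty", {
  seq <- random_dna(1000)
  suppressWarnings(m <- train_coding_model(seq, genetic_code(11)))
  orfs <- find_orfs(seq, genetic_code(11))
  skip_if(nrow(orfs) == 0)
  scored <- score_orfs(orfs, seq, m, per_gene_penalty_bits = 6)
  expect_true(all(scored$score_bits == -6))
})

test_that("true genes outscore shuffled copies and intergenic windows", {
  ts <- generate_genome(generator_config(seed = 1, n_genes = 20))
  model <- train_coding_model(ts$seq, genetic_code(11))
  lo <- model$hexamer_logodds
  hexscore <- function(cds) {
    v <- match(strsplit(cds, "")[[1]], c("A", "C", "G", "T")) - 1
    st <- seq(1, length(v) - 5, 3)
    idx <- v[st] * 1024 + v[st + 1] * 256 + v[st + 2] * 64 +
      v[st + 3] * 16 + v[st + 4] * 4 + v[st + 5] + 1
    sum(lo[idx])
  }
  true_scores <- sapply(seq_len(nrow(ts$genes)), function(i)
    hexscore(gene_cds(ts, i)))
  set.seed(99)
  shuf_scores <- sapply(seq_len(nrow(ts$genes)), function(i) {
    cds <- gene_cds(ts, i)
    hexscore(paste(sample(strsplit(cds, "")[[1]]), collapse = ""))
  })
  expect_gt(mean(true_scores), mean(shuf_scores))

  # discrimination at n = 50: true genes positive, random windows negative
  ts2 <- generate_genome(generator_config(seed = 1, n_genes = 50))
  m2 <- train_coding_model(ts2$seq, genetic_code(11))
  g_scores <- sapply(seq_len(nrow(ts2$genes)), function(i)
    hexscore2(m2, gene_cds(ts2, i))) - 6
  set.seed(1)
  L <- nchar(ts2$seq)
  r_scores <- sapply(seq_len(nrow(ts2$genes)), function(i) {
    w <- ts2$genes$end[i] - ts2$genes$start[i]
    at <- sample(L - w, 1)
    s <- substr(ts2$seq, at, at + w - 1)
    hexscore2(m2, paste(sample(strsplit(s, "")[[1]]), collapse = ""))
  }) - 6
  expect_gte(mean(g_scores > 0), 0.9)
  expect_gte(mean(r_scores < 0), 0.9)
})

test_that("gene selection handles the trivial cases", {
  df <- data.frame(contig_id = "c", start = c(0, 200), end = c(150, 350),
                   strand = "+", score_bits = c(10, 5))
  expect_equal(nrow(select_genes(df)), 2)
  df$score_bits <- c(-1, -2)
  expect_equal(nrow(select_genes(df)), 0)
  expect_equal(nrow(select_genes(df[0, ])), 0)
})

test_that("DP selection matches exhaustive subset search", {
  set.seed(5)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    start <- sort(sample(0:900, n))
    len <- sample(seq(60, 300, 3), n, replace = TRUE)
    df <- data.frame(start = start, end = start + len,
                     score_bits = round(runif(n, -2, 10), 3))
    got <- select_genes(df, max_overlap_nt = 30)
    expect_equal(sum(got$score_bits), best_subset_score(df, 30),
                 tolerance = 1e-9)
  }
})

test_that("total selected score is monotone in the overlap allowance", {
  ts <- generate_genome(generator_config(seed = 8, n_genes = 25))
  orfs <- find_orfs(ts$seq, genetic_code(11))
  m <- train_coding_model(ts$seq, genetic_code(11))
  scored <- score_orfs(orfs, ts$seq, m)
  totals <- sapply(c(0, 15, 30, 60, 120), function(ov)
    sum(select_genes(scored, ov)$score_bits))
  expect_true(all(diff(totals) >= -1e-9))
})

test_that("call_genes recovers most true genes with exact stop coordinates", {
  ts <- generate_genome(generator_config(seed = 1, n_genes = 30))
  calls <- call_genes(ts$seq, genetic_code(11))
  key <- function(df) ifelse(df$strand == "+", paste0("+", df$end),
                             paste0("-", df$start))
  expect_gte(mean(key(ts$genes) %in% key(calls)), 0.8)
  # selected genes carry no internal stop under the calling code
  code <- genetic_code(11)
  for (i in seq_len(nrow(calls))) {
    cds <- substr(ts$seq, calls$start[i] + 1, calls$end[i])
    if (calls$strand[i] == "-") cds <- reverse_complement(cds)
    aa <- translate_cds(cds, code)
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("reassigned genomes are truncated under table 11 but not table 15", {
  ts <- generate_genome(generator_config(seed = 1, n_genes = 30,
                                         code_id = 15))
  c15 <- call_genes(ts$seq, genetic_code(15))
  c11 <- call_genes(ts$seq, genetic_code(11))
  true_med <- median(ts$genes$end - ts$genes$start)
  med15 <- median(c15$end - c15$start)
  expect_lt(abs(med15 - true_med) / true_med, 0.15)
  expect_lt(median(c11$end - c11$start), med15)
})

test_that("called coding capacity tracks truth under the correct code", {
  errs <- sapply(1:10, function(s) {
    ts <- generate_genome(generator_config(seed = s))
    calls <- call_genes(ts$seq, genetic_code(11))
    coding_capacity(calls[, c("start", "end")], nchar(ts$seq)) -
      coding_capacity(ts$genes, nchar(ts$seq))
  })
  expect_lt(abs(mean(errs)), 8)
})
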