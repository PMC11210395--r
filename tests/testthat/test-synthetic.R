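test_that("generation is a deterministic function of the config", {
  cfg <- generator_config(seed = 9, n_genes = 15, code_id = 15)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$genes, b$genes)
  expect_error(generator_config(n_genes = 100000,
                                gene_len_median_nt = 1000), "infeasible")
})

test_that("true genes are well-formed under the true code", {
  for (id in c("11", "15", "4")) {
    ts <- generate_genome(generator_config(seed = 10, n_genes = 15,
                                           code_id = id))
    code <- genetic_code(id)
    for (i in seq_len(nrow(ts$genes))) {
      aa <- translate_cds(gene_cds(ts, i), code)
      first_codon <- substr(gene_cds(ts, i), 1, 3)
      expect_true(first_codon %in% code$start_set)
      expect_equal(aa[length(aa)], "*")
      expect_false(any(aa[-length(aa)] == "*"))
    }
  }
})

test_that("reassigned codon usage matches the configured rate", {
  ts <- generate_genome(generator_config(seed = 1, n_genes = 30,
                                         code_id = 15, q = 0.3))
  expect_gte(mean(ts$genes$n_reassigned >= 1), 0.6)
  # recorded counts equal the in-frame TAG count of each gene
  for (i in seq_len(nrow(ts$genes))) {
    cds <- gene_cds(ts, i)
    n <- nchar(cds) / 3
    codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    expect_equal(sum(codons == "TAG"), ts$genes$n_reassigned[i])
  }
  # q = 0 never swaps
  ts0 <- generate_genome(generator_config(seed = 1, n_genes = 10,
                                          code_id = 15, q = 0))
  expect_true(all(ts0$genes$n_reassigned == 0))
})

test_that("truth density and GC follow the configured distributions", {
  cfg <- generator_config(seed = 1)
  dens <- sapply(1:10, function(s) {
    ts <- generate_genome(generator_config(seed = s))
    coding_capacity(ts$genes, nchar(ts$seq))
  })
  # analytic expectation: mean gene / (mean gene + mean gap)
  mean_gene <- cfg$gene_len_median_nt * exp(cfg$gene_len_sigma^2 / 2)
  expected <- 100 * mean_gene / (mean_gene + cfg$intergenic_mean_nt)
  expect_lt(abs(mean(dens) - expected), 5)

  gcs <- sapply(1:10, function(s) {
    ts <- generate_genome(generator_config(seed = s, gc = 0.45))
    v <- strsplit(ts$seq, "")[[1]]
    100 * mean(v %in% c("G", "C"))
  })
  expect_true(all(abs(gcs - 45) < 3))
})

test_that("table-11 reading truncates each reassigned gene at its first TAG", {
  ts <- generate_genome(generator_config(seed = 2, n_genes = 25,
                                         code_id = 15, q = 0.3))
  o11 <- find_orfs(ts$seq, genetic_code(11), min_len_nt = 9)
  n_checked <- 0
  for (i in seq_len(nrow(ts$genes))) {
    g <- ts$genes[i, ]
    cds <- gene_cds(ts, i)
    n <- nchar(cds) / 3
    codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    first_tag <- which(codons == "TAG")[1]
    if (is.na(first_tag)) next
    # any table-11 ORF reading this gene in frame must stop exactly at
    # the first TAG (the analytic truncation boundary); the ORF start may
    # reach upstream of the gene (first-start rule), and a truncation
    # shorter than min_len is simply not emitted
    if (g$strand == "+") {
      boundary <- g$start + 3 * first_tag
      inframe <- o11$strand == "+" & o11$start <= g$start &
        o11$end > g$start & (o11$start - g$start) %% 3 == 0
      expect_true(all(o11$end[inframe] == boundary))
    } else {
      boundary <- g$end - 3 * first_tag
      inframe <- o11$strand == "-" & o11$end >= g$end &
        o11$start < g$end & (o11$end - g$end) %% 3 == 0
      expect_true(all(o11$start[inframe] == boundary))
    }
    n_checked <- n_checked + sum(inframe)
  }
  # most truncations are long enough to be observed as ORFs
  expect_gt(n_checked, 0.8 * sum(ts$genes$n_reassigned >= 1))
})

test_that("tRNA embedding shifts bookkeeping but not gene content", {
  base <- generate_genome(generator_config(seed = 11, n_genes = 12))
  emb <- embed_trna(base, "CTA")
  expect_equal(nchar(emb$seq), nchar(base$seq) + 76)
  expect_equal(emb$trna$end - emb$trna$start, 76)
  expect_equal(substr(emb$seq, emb$trna$start + 1, emb$trna$end),
               build_trna_cassette("CTA"))
  # every gene's sequence is unchanged after the shift
  for (i in seq_len(nrow(base$genes))) {
    expect_identical(gene_cds(emb, i), gene_cds(base, i))
  }
  expect_error(embed_trna(base, "CTA", position = base$genes$start[1] + 5),
               "intergenic")
})

test_that("truth files round-trip through the FASTA/GFF3 readers", {
  ts <- generate_genome(generator_config(seed = 12, n_genes = 10,
                                         code_id = 15,
                                         embed_trna = "CTA"))
  prefix <- file.path(tempdir(), "truth_rt")
  paths <- write_truth(ts, prefix)
  recs <- read_fasta(paths[1])
  expect_equal(nrow(recs), 1)
  expect_identical(recs$sequence, ts$seq)
  expect_identical(recs$id, ts$contig_id)
  feats <- read_gff3(paths[2])
  cds <- feats[feats$type == "CDS", ]
  expect_equal(cds$start, ts$genes$start)
  expect_equal(cds$end, ts$genes$end)
  expect_equal(cds$strand, ts$genes$strand)
  expect_true(all(cds$transl_table == "15"))
  trna <- feats[feats$type == "tRNA", ]
  expect_equal(c(trna$start, trna$end), c(ts$trna$start, ts$trna$end))
  cfg <- jsonlite::read_json(paths[3])
  expect_equal(cfg$config$seed, 12)
  expect_equal(cfg$code_id, "15")
  # FASTA dialect: uppercase, 60-column lines
  lines <- readLines(paths[1])
  body <- lines[-1]
  expect_true(all(nchar(body) <= 60))
  expect_false(any(grepl("[a-z]", body)))
  unlink(paths)
})
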