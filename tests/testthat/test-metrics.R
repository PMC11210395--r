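test_that("coding capacity merges overlaps and matches mask counting", {
  expect_equal(coding_capacity(data.frame(start = 0, end = 500), 1000), 50)
  expect_equal(coding_capacity(
    data.frame(start = c(0, 400), end = c(600, 800)), 1000), 80)
  expect_equal(coding_capacity(data.frame(start = numeric(0),
                                          end = numeric(0)), 1000), 0)
  expect_error(coding_capacity(data.frame(start = -1, end = 10), 100),
               "intervals")
  expect_error(coding_capacity(data.frame(start = 0, end = 101), 100),
               "intervals")
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(1:20, 1)
    L <- sample(200:2000, 1)
    s <- sample(0:(L - 10), n, replace = TRUE)
    e <- pmin(s + sample(5:300, n, replace = TRUE), L)
    iv <- data.frame(start = s, end = e)
    expect_equal(coding_capacity(iv, L), mask_capacity(iv, L))
  }
  # permutation and strand invariance
  iv <- data.frame(start = c(10, 50, 30), end = c(40, 90, 70))
  expect_equal(coding_capacity(iv, 100),
               coding_capacity(iv[c(3, 1, 2), ], 100))
})

test_that("median gene length follows the sort-and-midpoint rule", {
  expect_equal(median_gene_length(
    data.frame(start = c(0, 0, 0), end = c(300, 600, 900))), 600)
  expect_equal(median_gene_length(
    data.frame(start = c(0, 0), end = c(300, 600))), 450)
  expect_warning(z <- median_gene_length(data.frame(start = numeric(0),
                                                    end = numeric(0))),
                 "no genes")
  expect_equal(z, 0)
  set.seed(32)
  for (rep in 1:100) {
    lens <- sample(90:3000, sample(1:30, 1), replace = TRUE)
    got <- median_gene_length(data.frame(start = 0, end = lens))
    srt <- sort(lens)
    n <- length(srt)
    want <- if (n %% 2 == 1) srt[(n + 1) / 2] else
      (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(got, want)
  }
})

test_that("dataset summaries take the median of per-genome medians", {
  expect_equal(median_of_genome_medians(c(2, 20)), 11)
  expect_equal(median_of_genome_medians(7), 7)
  set.seed(33)
  for (rep in 1:50) {
    x <- runif(sample(1:20, 1), 100, 900)
    expect_equal(median_of_genome_medians(x), median(x))
  }
})

test_that("hypothetical fraction counts the unannotated label", {
  expect_equal(hypothetical_fraction(
    c("hypothetical", "hypothetical", "hypothetical", "capsid")), 75)
  expect_equal(hypothetical_fraction(rep("terminase", 10)), 0)
  labs <- c(rep("hypothetical", 83), rep("portal", 17))
  expect_equal(hypothetical_fraction(labs), 83)
})

test_that("percent increase reproduces printed-precision arithmetic", {
  expect_equal(percent_increase(350, 518), 48.0)
  expect_equal(percent_increase(573, 588), 2.6)
  # 318 -> 550 is 72.9559...%, which is 73.0 at one decimal half-up
  expect_equal(percent_increase(318, 550), 73.0)
  expect_equal(percent_increase(500, 500), 0.0)
  expect_equal(percent_increase(100, 50), -50.0)
  expect_error(percent_increase(0, 10), "before")
})

test_that("paired t test matches the closed form and flags degenerate input", {
  res <- paired_t_test(c(1, 2, 3), c(2, 4, 3))
  expect_equal(res$t, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.2254033, tolerance = 1e-6)
  expect_error(paired_t_test(1, 2), "degenerate")
  expect_error(paired_t_test(c(1, 2), c(3, 4)), "degenerate")
  expect_error(paired_t_test(c(1, 2), c(1, 2, 3)), "equal length")
  # direction: a constant shift with noise keeps the sign of the shift
  set.seed(34)
  a <- runif(20)
  expect_gt(paired_t_test(a, a + 3 + rnorm(20, 0, 0.1))$t, 0)
  expect_lt(paired_t_test(a, a - 3 + rnorm(20, 0, 0.1))$t, 0)
  # closed-form oracle on random pairs
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n, 0.5)
    got <- paired_t_test(a, b)
    d <- b - a
    t_want <- mean(d) / (sd(d) / sqrt(n))
    p_want <- 2 * pt(-abs(t_want), n - 1)
    expect_equal(got$t, t_want, tolerance = 1e-10)
    expect_equal(got$df, n - 1)
    expect_equal(got$p, p_want, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the step-up brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(35)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("strategy comparison pairs genomes and adjusts across metrics", {
  set.seed(36)
  make_ann <- function(shift) {
    lapply(1:8, function(i) {
      s <- sort(sample(0:4000, 6)) * 2
      data.frame(start = s, end = s + 300 + shift + sample(0:30, 6, TRUE))
    })
  }
  a <- make_ann(0); b <- make_ann(200)
  names(a) <- names(b) <- paste0("g", 1:8)
  lens <- setNames(rep(10000, 8), names(a))
  cmp <- compare_strategies(a, b, lens)
  expect_equal(nrow(cmp), 3)
  expect_true(all(c("p_value_raw", "p_value_bh") %in% names(cmp)))
  expect_true(all(cmp$p_value_bh >= cmp$p_value_raw, na.rm = TRUE))
  row <- cmp[cmp$metric == "median_gene_len_nt", ]
  expect_gt(row$mean_diff, 0)
  # swapping the strategies negates the t statistics exactly
  rev <- compare_strategies(b, a, lens)
  expect_equal(rev$t_statistic, -cmp$t_statistic, tolerance = 1e-12)
  # identical strategies degenerate to NA tests with zero differences
  same <- compare_strategies(a, a, lens)
  expect_true(all(same$mean_diff == 0))
  expect_true(all(is.na(same$p_value_raw)))
  # with labels, the hypothetical-fraction metric joins the family
  labs <- lapply(a, function(g)
    sample(c("hypothetical", "x"), nrow(g), TRUE))
  cmp4 <- compare_strategies(a, b, lens, labels_a = labs, labels_b = labs)
  expect_equal(nrow(cmp4), 4)
})
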