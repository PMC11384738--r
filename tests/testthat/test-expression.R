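test_that("DEG filtering uses inclusive thresholds", {
  expr <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    log2fc = c(1.0, 0.4, -0.6, 2.0, -0.5, 0.0),
    padj = c(0.01, 0.01, 0.04, 0.20, 0.05, 1.0))
  degs <- filter_degs(expr)
  expect_setequal(degs$all, c("g1", "g3", "g5"))
  expect_setequal(degs$up, "g1")
  expect_setequal(degs$down, c("g3", "g5"))
  expect_length(filter_degs(expr, alpha = 0)$all, 0)
  expect_setequal(filter_degs(expr, alpha = 1, min_abs_log2fc = 0)$all,
                  expr$gene_id)
  expect_error(filter_degs(expr, contrast = "missing"), "contrast not found")
})

test_that("relaxing DEG thresholds never shrinks the set", {
  set.seed(61)
  expr <- data.frame(gene_id = sprintf("g%d", 1:200),
                     log2fc = rnorm(200), padj = runif(200))
  strict <- filter_degs(expr, alpha = 0.02, min_abs_log2fc = 1)$all
  looser_a <- filter_degs(expr, alpha = 0.2, min_abs_log2fc = 1)$all
  looser_f <- filter_degs(expr, alpha = 0.02, min_abs_log2fc = 0.2)$all
  expect_true(all(strict %in% looser_a))
  expect_true(all(strict %in% looser_f))
})

test_that("rank-sum test reproduces exact enumeration", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)
  expect_true(r$exact)
  # identical samples sit at the null centre under the approximation
  x <- rep(c(1, 2, 3), 4)
  expect_gte(rank_sum_test(x, x)$p_value, 0.99)
  # strong shift at n = m = 50
  expect_lt(rank_sum_test(51:100, 1:50)$p_value, 1e-10)
  # random tie-free inputs vs the C(n+m, n) enumeration oracle
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    v <- sample(1000, n + m) / 7
    a <- v[seq_len(n)]; b <- v[-seq_len(n)]
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(rank_sum_test(a, b, alt)$p_value,
                   oracle_rank_sum_p(a, b, alt), tolerance = 1e-12)
    }
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank test reproduces exact enumeration", {
  expect_equal(signed_rank_test(c(1, -1))$p_value, 1.0)
  expect_equal(signed_rank_test(c(1, 2, 3), "greater")$p_value, 1 / 8)
  # rank-based: invariant to positive scaling
  d <- c(3, -1, 4, 1.5, -5, 9)
  expect_equal(signed_rank_test(d)$p_value, signed_rank_test(2 * d)$p_value)
  # zeros are dropped before ranking
  expect_equal(signed_rank_test(c(0, 1, 2, 3), "greater")$p_value, 1 / 8)
  expect_error(signed_rank_test(c(0, 0)), "all paired differences")
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    d <- sample(1000, n) / 9 * sample(c(-1, 1), n, replace = TRUE)
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(signed_rank_test(d, alt)$p_value,
                   oracle_signed_rank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("trajectory summaries z-normalise per gene", {
  tpm <- rbind(flat = rep(5, 4),
               up = c(1, 2, 3, 4),
               up2 = c(10, 20, 30, 40))
  colnames(tpm) <- paste0("t", 0:3)
  s_flat <- trajectory_summary(tpm, "flat")
  expect_equal(s_flat$mean, rep(0, 4))
  s_up <- trajectory_summary(tpm, "up")
  expect_true(all(diff(s_up$mean) > 0))
  # two genes with identical shapes: zero sd at every timepoint
  s_pair <- trajectory_summary(tpm, c("up", "up2"))
  expect_equal(s_pair$sd, rep(0, 4))
  expect_error(trajectory_summary(tpm, character(0)), "empty gene group")
  expect_error(trajectory_summary(tpm[, 1, drop = FALSE], "up"),
               "two timepoints")
})

test_that("CUT&RUN normalisation follows the stated ratio scheme", {
  tab <- cutrun_fixture()
  res <- cutrun_relative_signal(tab, "ctrl")
  ctrl <- res[res$sample_id == "ctrl", ]
  expect_equal(ctrl$fold_vs_control, c(1, 1))
  kd_e1 <- res$fold_vs_control[res$sample_id == "kd" &
                                 res$amplicon_id == "e1"]
  # kd e1: (8/2)/2 = 2 vs ctrl (4/2)/1 = 2 -> fold 1
  expect_equal(kd_e1, 1.0)
  # identical treatment and control signals give fold 1 everywhere
  tab2 <- tab
  tab2$signal[tab2$sample_id == "kd"] <-
    tab2$signal[tab2$sample_id == "ctrl"]
  expect_true(all(cutrun_relative_signal(tab2, "ctrl")$fold_vs_control == 1))
})

test_that("doubling a sample's spike-in halves its fold change", {
  tab <- cutrun_fixture()
  res0 <- cutrun_relative_signal(tab, "ctrl")
  tab$signal[tab$sample_id == "kd" & tab$role == "spike_in"] <-
    2 * tab$signal[tab$sample_id == "kd" & tab$role == "spike_in"]
  res2 <- cutrun_relative_signal(tab, "ctrl")
  kd0 <- res0$fold_vs_control[res0$sample_id == "kd"]
  kd2 <- res2$fold_vs_control[res2$sample_id == "kd"]
  expect_equal(kd2, kd0 / 2)
})

test_that("global scaling of one sample cancels except through the spike-in", {
  set.seed(64)
  for (rep in 1:100) {
    sig <- runif(8, 0.5, 20)
    tab <- cutrun_fixture()
    tab$signal <- sig
    res0 <- cutrun_relative_signal(tab, "ctrl")
    const <- runif(1, 0.1, 10)
    tab$signal[tab$sample_id == "kd"] <-
      tab$signal[tab$sample_id == "kd"] * const
    res1 <- cutrun_relative_signal(tab, "ctrl")
    # target/background ratio is invariant; only the spike-in term scales
    expect_equal(res1$fold_vs_control[res1$sample_id == "kd"],
                 res0$fold_vs_control[res0$sample_id == "kd"] / const,
                 tolerance = 1e-12)
  }
})

test_that("CUT&RUN input validation and Ct mode work", {
  tab <- cutrun_fixture()
  expect_error(cutrun_relative_signal(tab, "absent"), "control sample")
  bad <- tab[tab$role != "spike_in", ]
  expect_error(cutrun_relative_signal(bad, "ctrl"), "spike_in")
  neg <- tab; neg$signal[1] <- 0
  expect_error(cutrun_relative_signal(neg, "ctrl"), "positive")
  # Ct mode: converting Ct to 2^(-Ct) reproduces the linear-scale result
  ct <- tab; ct$signal <- -log2(tab$signal)
  expect_equal(cutrun_relative_signal(ct, "ctrl", input = "ct")$fold_vs_control,
               cutrun_relative_signal(tab, "ctrl")$fold_vs_control)
})

test_that("expression table IO validates ids and padj", {
  p <- withr::local_tempfile(fileext = ".tsv")
  expr <- expr_table(c("a", "b"), c(1, -1), c(0.1, 0.9))
  write_expression(expr, p)
  expect_equal(read_expression(p), expr)
  writeLines("gene_id\tlog2fc\tpadj\na\t1\t2", p)
  expect_error(read_expression(p), "padj")
  writeLines("gene_id\tlog2fc\tpadj\na\t1\t0.5\na\t2\t0.5", p)
  expect_error(read_expression(p), "duplicate")
})
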