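test_that("the default genome is one 10 Mb chromosome and deterministic", {
  g <- generate_genome(sim_config())
  expect_equal(g$chrom_names, "chr1")
  expect_equal(unname(g$chrom_lengths), 1e7)
  expect_identical(generate_genome(sim_config(seed = 4)),
                   generate_genome(sim_config(seed = 4)))
  expect_error(sim_config(chrom_lengths = 0), "positive")
  expect_error(sim_config(chrom_names = c("a", "a"),
                          chrom_lengths = c(10, 10)), "unique")
})

test_that("config validation catches bad probability vectors and counts", {
  expect_error(sim_config(enhancer_composition = list(
    cond1 = c(stateA_specific = 0.5, stateB_specific = 0.5,
              shared = 0.5, background = -0.5))), "probability vector")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_genes = -5), "counts")
})

test_that("gene generation respects spacing, uniqueness and feasibility", {
  g <- generate_genome(sim_config())
  expect_equal(nrow(generate_genes(g, 0)), 0L)
  genes <- generate_genes(g, 100, min_spacing = 50000, seed = 2)
  tss <- sort(genes$tss)
  expect_true(all(diff(tss) >= 50000))  # pairwise scan via sorted gaps
  many <- generate_genes(g, 1000, min_spacing = 5000, seed = 3)
  expect_equal(anyDuplicated(many$gene_id), 0L)
  expect_error(generate_genes(g, 1000, min_spacing = 50000),
               "cannot place")
  expect_identical(generate_genes(g, 50, 20000, seed = 7),
                   generate_genes(g, 50, 20000, seed = 7))
})

test_that("enhancers avoid TSS windows and never overlap across classes", {
  cfg <- sim_config(n_enhancers_per_class = c(stateA_specific = 40,
                                              stateB_specific = 40,
                                              shared = 40), seed = 5)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg$n_genes, cfg$min_spacing, cfg$seed)
  enh <- generate_enhancers(genome, genes, cfg)
  expect_equal(vapply(enh, length, 0L),
               c(stateA_specific = 40L, stateB_specific = 40L,
                 shared = 40L))
  # brute-force scan: no enhancer within 3 kb of any TSS
  all_enh <- do.call(rbind, lapply(enh, gr_to_df))
  for (i in seq_len(nrow(all_enh))) {
    d_ok <- all(genes$tss + 3000 < all_enh$start[i] |
                  genes$tss - 3000 >= all_enh$end[i])
    expect_true(d_ok)
  }
  # class exclusivity: no base covered twice
  expect_null(oracle_pairs(do.call(rbind, lapply(enh[1:2], gr_to_df)),
                           gr_to_df(enh$shared)))
  expect_null(oracle_pairs(gr_to_df(enh$stateA_specific),
                           gr_to_df(enh$stateB_specific)))
})

test_that("impossible enhancer placement errors out", {
  cfg <- sim_config(chrom_lengths = 50000, n_genes = 2,
                    min_spacing = 10000, tss_exclusion = 100000,
                    n_enhancers_per_class = c(stateA_specific = 5,
                                              stateB_specific = 5,
                                              shared = 5))
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, 2, 10000, cfg$seed)
  expect_error(generate_enhancers(genome, genes, cfg), "window covers|could not place")
})

test_that("peak composition labels are exact at the extremes", {
  cfg <- sim_config(seed = 6)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg$n_genes, cfg$min_spacing, cfg$seed)
  enh <- generate_enhancers(genome, genes, cfg)
  all_enh <- df_to_gr(do.call(rbind, lapply(enh, gr_to_df)))
  bg_only <- sim_config(seed = 6, n_peaks_per_condition = c(cond1 = 300, cond2 = 10),
                        enhancer_composition = list(
                          cond1 = c(stateA_specific = 0, stateB_specific = 0,
                                    shared = 0, background = 1),
                          cond2 = cfg$enhancer_composition$cond2))
  pk_bg <- generate_peaks(genome, enh, bg_only, "cond1", 1)[[1]]
  expect_equal(sum(IRanges::overlapsAny(pk_bg, all_enh)), 0L)
  b_only <- sim_config(seed = 6, n_peaks_per_condition = c(cond1 = 300, cond2 = 10),
                       enhancer_composition = list(
                         cond1 = c(stateA_specific = 0, stateB_specific = 1,
                                   shared = 0, background = 0),
                         cond2 = cfg$enhancer_composition$cond2))
  pk_b <- generate_peaks(genome, enh, b_only, "cond1", 1)[[1]]
  expect_true(all(IRanges::overlapsAny(pk_b, enh$stateB_specific)))
})

test_that("realised composition converges to the planted vector", {
  cfg <- sim_config(seed = 8,
                    n_peaks_per_condition = c(cond1 = 10, cond2 = 2000),
                    enhancer_composition = list(
                      cond1 = c(stateA_specific = 0.25, stateB_specific = 0.25,
                                shared = 0.25, background = 0.25),
                      cond2 = c(stateA_specific = 0.10, stateB_specific = 0.74,
                                shared = 0.06, background = 0.10)))
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg$n_genes, cfg$min_spacing, cfg$seed)
  enh <- generate_enhancers(genome, genes, cfg)
  pk <- generate_peaks(genome, enh, cfg, "cond2", 1)[[1]]
  frac <- mean(IRanges::overlapsAny(pk, enh$stateB_specific))
  expect_lt(abs(frac - 0.74), 0.03)
})

test_that("empty enhancer classes with nonzero probability error out", {
  cfg <- sim_config(n_enhancers_per_class = c(stateA_specific = 0,
                                              stateB_specific = 10,
                                              shared = 10), seed = 9)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg$n_genes, cfg$min_spacing, cfg$seed)
  enh <- generate_enhancers(genome, genes, cfg)
  expect_error(generate_peaks(genome, enh, cfg, "cond1", 1),
               "no enhancers")
  expect_error(generate_peaks(genome, enh, cfg, "weird", 1),
               "no composition")
})

test_that("replicates are jittered copies clipped to the genome", {
  cfg <- sim_config(seed = 10, replicate_jitter_sd = 30)
  genome <- generate_genome(cfg)
  genes <- generate_genes(genome, cfg$n_genes, cfg$min_spacing, cfg$seed)
  enh <- generate_enhancers(genome, genes, cfg)
  reps <- generate_peaks(genome, enh, cfg, "cond1", 3)
  expect_length(reps, 3L)
  for (r in reps) {
    df <- gr_to_df(r)
    expect_true(all(df$start >= 0))
    expect_true(all(df$end <= 1e7))
    expect_true(all(df$end - df$start >= 50))
  }
  expect_identical(gr_to_df(generate_peaks(genome, enh, cfg, "cond1", 2)[[2]]),
                   gr_to_df(reps[[2]]))
})

test_that("planted expression effects are exact without noise", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:30), chrom = "chr1",
                      strand = "+", tss = seq(1e4, 3e5, length.out = 30))
  tg <- target_groups(sprintf("g%d", 1:5), sprintf("g%d", 6:10),
                      sprintf("g%d", 11:15))
  cfg <- sim_config(noise_sd = 0, effect_sizes = c(cond1_specific = 1,
                                                   cond2_specific = -2,
                                                   shared = 0))
  expr <- generate_expression(genes, tg, cfg)
  expect_equal(expr$log2fc[1:5], rep(1, 5))
  expect_equal(expr$log2fc[6:10], rep(-2, 5))
  expect_equal(expr$log2fc[11:30], rep(0, 20))
  expect_equal(expr$padj[1:10], rep(0, 10))
  expect_equal(expr$padj[11:30], rep(1, 20))
})

test_that("null expression group means obey the central-limit bound", {
  n <- 2000
  genes <- data.frame(gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                      strand = "+", tss = seq_len(n) * 4000)
  grp <- sprintf("g%04d", 1:400)
  tg <- target_groups(grp, character(0), character(0))
  cfg <- sim_config(noise_sd = 0.5, chrom_lengths = 1e7 * 4,
                    effect_sizes = c(cond1_specific = 0,
                                     cond2_specific = 0, shared = 0),
                    seed = 12)
  expr <- generate_expression(genes, tg, cfg)
  expect_lt(abs(mean(expr$log2fc[expr$group == "cond1_specific"])),
            3 * 0.5 / sqrt(400))
  expect_identical(generate_expression(genes, tg, cfg),
                   generate_expression(genes, tg, cfg))
  bad <- target_groups("absent", character(0), character(0))
  expect_error(generate_expression(genes, bad, cfg), "unknown genes")
})

test_that("optional timepoint columns follow the planted trend", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:40), chrom = "chr1",
                      strand = "+", tss = seq(1e4, 4e5, length.out = 40))
  tg <- target_groups(sprintf("g%d", 1:10), sprintf("g%d", 11:20),
                      character(0))
  cfg <- sim_config(n_timepoints = 5, noise_sd = 0.2,
                    effect_sizes = c(cond1_specific = -2,
                                     cond2_specific = 2, shared = 0))
  expr <- generate_expression(genes, tg, cfg)
  tpm <- as.matrix(expr[, grepl("^tpm_", names(expr))])
  rownames(tpm) <- expr$gene_id
  expect_equal(ncol(tpm), 5L)
  s_down <- trajectory_summary(tpm, sprintf("g%d", 1:10))
  s_up <- trajectory_summary(tpm, sprintf("g%d", 11:20))
  expect_lt(s_down$mean[5], s_down$mean[1])
  expect_gt(s_up$mean[5], s_up$mean[1])
})

test_that("accessible-region generation is deterministic and in bounds", {
  genome <- generate_genome(sim_config())
  a1 <- generate_accessible_regions(genome, 500, width = 400, seed = 13)
  a2 <- generate_accessible_regions(genome, 500, width = 400, seed = 13)
  expect_identical(gr_to_df(a1), gr_to_df(a2))
  df <- gr_to_df(a1)
  expect_equal(nrow(df), 500L)
  expect_true(all(df$start >= 0 & df$end <= 1e7))
  expect_true(all(df$end - df$start == 400))
  expect_equal(region_label(a1), "accessible")
})
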