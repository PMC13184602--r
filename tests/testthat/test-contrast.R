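records <- function(ids, levels, methylated = TRUE, sample_id = "s") {
  data.frame(gene_id = ids, sample_id = sample_id,
             n_exonic_sites = 10L, meth_reads_sum = 1L, total_reads_sum = 10L,
             level_pct = levels, n_cpg = 1L, n_chg = 1L, n_chh = 1L,
             n_hyper_positions = 0L,
             is_methylated_gene = rep_len(methylated, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("per-gene deltas subtract reference from test levels", {
  d <- per_gene_deltas(records("g1", 35), records("g1", 20))
  expect_equal(d$delta, 15)
  # identical samples give all-zero deltas
  r <- records(c("g1", "g2"), c(10, 20))
  expect_equal(per_gene_deltas(r, r)$delta, c(0, 0))
})

test_that("the gene universe is methylated-in-either restricted to covered-in-both", {
  test_r <- records(c("g1", "g2", "g3", "g5"), c(10, 20, 30, 40),
                    methylated = c(TRUE, FALSE, TRUE, TRUE))
  ref_r <- records(c("g1", "g2", "g4"), c(5, 10, 15),
                   methylated = c(FALSE, FALSE, TRUE))
  expect_message(d <- per_gene_deltas(test_r, ref_r), "dropped")
  # brute-force set arithmetic oracle
  meth_union <- union(c("g1", "g3", "g5"), "g4")
  covered_both <- intersect(test_r$gene_id, ref_r$gene_id)
  expect_setequal(d$gene_id, intersect(meth_union, covered_both))
  # nothing methylated anywhere -> contrast error
  expect_error(
    suppressMessages(per_gene_deltas(records("g1", 0, methylated = FALSE),
                                     records("g1", 0, methylated = FALSE))),
    "empty gene universe")
})

test_that("median shift and loci variability follow their definitions", {
  ms <- median_shift(c(4, 4, 4))
  expect_equal(ms$median_diff, 4)
  expect_equal(ms$sd_loci, 0)
  d <- c(-1, 0, 2, 3, 5)
  # sorting oracle: middle order statistic for odd n
  expect_equal(median_shift(d)$median_diff, sort(d)[3L])
  # even n: mean of the central pair
  expect_equal(median_shift(c(1, 2, 10, 20))$median_diff, 6)
  expect_equal(median_shift(c(1, 3))$sd_loci, sqrt(2))
})

test_that("signed-rank p-values match full enumeration and symmetry", {
  spec <- contrast_spec("t", "r")
  # n = 6 all-positive deltas: exact two-sided p by 2^6 enumeration
  d6 <- c(1, 2, 3, 4, 5, 6)
  wb <- wilcoxon_bh(list(s1 = d6), spec)
  expect_equal(wb$p_value, 0.03125)
  expect_equal(wb$p_value, oracle_signed_rank_p(d6))
  # deltas perfectly symmetric about zero
  wb <- wilcoxon_bh(list(s1 = c(1, -1, 2, -2)), spec)
  expect_equal(wb$p_value, 1)
  # all zeros: degenerate, p = 1
  wb <- wilcoxon_bh(list(s1 = c(0, 0, 0)), spec)
  expect_true(wb$degenerate)
  expect_equal(wb$p_value, 1)
  expect_equal(wb$n_nonzero, 0L)
  # zeros are dropped before ranking
  expect_equal(wilcoxon_bh(list(s1 = c(0, d6)), spec)$p_value, 0.03125)
})

test_that("BH adjustment across a stage family matches the step-up formula", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(oracle_bh(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.03))
  # package q-values equal the hand-computed step-up on its own p-values
  set.seed(7)
  fam <- list(a = rnorm(12, 0.5), b = rnorm(12), c = rnorm(12, 1))
  wb <- wilcoxon_bh(fam, contrast_spec("t", "r"))
  expect_equal(wb$q_value, oracle_bh(wb$p_value))
  expect_true(all(wb$q_value >= wb$p_value))
  # q monotone in p
  expect_equal(order(wb$q_value), order(wb$p_value))
})

test_that("DMG calling applies the absolute-delta threshold", {
  spec <- contrast_spec("t", "r", dmg_delta_threshold = 10)
  d <- data.frame(gene_id = c("g1", "g2", "g3"), delta = c(15, 5, -12))
  out <- call_dmgs(d, spec)
  expect_setequal(out$dmg_ids, c("g1", "g3"))
  expect_equal(out$n_dmg, 2L)
  # threshold 0 selects genes with nonzero delta
  spec0 <- contrast_spec("t", "r", dmg_delta_threshold = 0)
  d0 <- data.frame(gene_id = c("g1", "g2"), delta = c(0, 3))
  expect_equal(call_dmgs(d0, spec0)$dmg_ids, "g2")
})

test_that("DMG sets shrink monotonically with the threshold", {
  set.seed(31)
  d <- data.frame(gene_id = sprintf("g%03d", 1:200),
                  delta = rnorm(200, 0, 12))
  s10 <- call_dmgs(d, contrast_spec("t", "r", dmg_delta_threshold = 10))
  s20 <- call_dmgs(d, contrast_spec("t", "r", dmg_delta_threshold = 20))
  expect_true(all(s20$dmg_ids %in% s10$dmg_ids))
  # brute-force check of the selection itself
  expect_setequal(s10$dmg_ids, d$gene_id[abs(d$delta) >= 10])
})

test_that("percent change keeps sign and satisfies the reversal identity", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 119), 19)
  expect_equal(percent_change(200, 150), -25)
  expect_warning(out <- percent_change(0, 5), "zero reference")
  expect_true(is.na(out))
  # metamorphic identity: pc(a,b) = -pc(b,a) * b / a
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:10000, 1); b <- sample(1:10000, 1)
    expect_equal(percent_change(a, b), -percent_change(b, a) * b / a)
  }
})

test_that("ANOVA with LSD letters separates distinct groups", {
  counts <- data.frame(
    sample_id = rep(c("ctl", "drt"), each = 3L),
    context = "CpG", chrom = rep(paste0("chr", 1:3), 2L),
    n_hyper_exonic = c(10L, 10L, 10L, 100L, 100L, 100L))
  res <- anova_lsd(counts)
  # zero residual variance with distinct means: infinite F, p = 0
  expect_equal(res$p_value, 0)
  expect_true(is.infinite(res$f_statistic))
  expect_true(res$anova_significant)
  expect_equal(length(unique(res$groups$letter)), 2L)
})

test_that("identical constant groups share one letter", {
  counts <- data.frame(
    sample_id = rep(c("a", "b"), each = 3L), context = "CpG",
    chrom = rep(paste0("chr", 1:3), 2L), n_hyper_exonic = 7L)
  res <- anova_lsd(counts)
  expect_false(isTRUE(res$anova_significant))
  expect_equal(unique(res$groups$letter), "a")
})

test_that("balanced two-group LSD agrees with the pooled-variance t-test", {
  set.seed(11)
  x <- rnorm(6, 50, 5); y <- rnorm(6, 60, 5)
  counts <- data.frame(
    sample_id = rep(c("a", "b"), each = 6L), context = "CpG",
    chrom = rep(paste0("chr", 1:6), 2L),
    n_hyper_exonic = c(x, y))
  res <- anova_lsd(counts)
  tt <- t.test(x, y, var.equal = TRUE)
  # with two groups the ANOVA F test and pooled t-test are the same test
  expect_equal(res$p_value, tt$p.value)
  if (res$anova_significant)
    expect_equal(unname(res$pairwise_p[1L, 2L]), tt$p.value)
  shared <- res$groups$letter[1L] == res$groups$letter[2L]
  expect_equal(shared, tt$p.value >= 0.05)
})

test_that("LSD letter sharing never contradicts the pairwise tests", {
  set.seed(13)
  counts <- expand.grid(chrom = paste0("chr", 1:4),
                        sample_id = c("ctl", "mid", "drt"),
                        context = c("CpG", "CHG"),
                        stringsAsFactors = FALSE)
  group_means <- c("ctl:CpG" = 100, "mid:CpG" = 104, "drt:CpG" = 160,
                   "ctl:CHG" = 60, "mid:CHG" = 100, "drt:CHG" = 100)
  mu <- group_means[paste(counts$sample_id, counts$context, sep = ":")]
  counts$n_hyper_exonic <- as.integer(round(rnorm(nrow(counts), mu, 8)))
  res <- anova_lsd(counts)
  if (res$anova_significant) {
    g <- res$groups
    for (i in seq_len(nrow(g) - 1L)) for (j in (i + 1L):nrow(g)) {
      share <- any(strsplit(g$letter[i], "")[[1L]] %in%
                     strsplit(g$letter[j], "")[[1L]])
      pij <- res$pairwise_p[g$group[i], g$group[j]]
      if (share) expect_gte(pij, res$alpha)
      if (!share) expect_lt(pij, res$alpha)
    }
  }
})

test_that("groups with too few observations are excluded with a warning", {
  counts <- data.frame(
    sample_id = c("a", "a", "a", "b"), context = "CpG",
    chrom = c("chr1", "chr2", "chr3", "chr1"),
    n_hyper_exonic = c(1L, 2L, 3L, 9L))
  expect_warning(expect_error(anova_lsd(counts), "at least 2 groups"),
                 "excluded")
})

test_that("stage variability is the n-1 standard deviation", {
  expect_equal(variability_across_stages(c(10, 10, 10)), 0)
  expect_equal(variability_across_stages(c(1, 3)), sqrt(2))
  # translation invariance
  x <- c(4, 9, 2, 7)
  expect_equal(variability_across_stages(x + 1000),
               variability_across_stages(x))
  expect_warning(out <- variability_across_stages(5), "fewer than 2")
  expect_true(is.na(out))
})

test_that("a full contrast recovers an imposed simulated shift", {
  cfg <- sim_config(genome_length = 100000L, n_chromosomes = 2L,
                    n_genes = 60L, gene_length = c(500L, 900L),
                    depth_mean = 20, effect_size = 8, affected_fraction = 1,
                    seed = 37L)
  g <- simulate_genome(cfg)
  recs <- lapply(c("control", "treated"), function(cond) {
    sim <- simulate_methylome(cfg, g$genome, g$models, cond)
    aggregate_genes(classify_sites(sim$report, g$models), g$models, cond)
  })
  res <- suppressMessages(
    contrast_genes(recs[[2L]], recs[[1L]], contrast_spec("treated", "control")))
  expect_gt(res$median_diff, 5)
  expect_lt(res$median_diff, 11)
  expect_true(res$wilcoxon$q_value < 0.05)
  expect_equal(res$n_genes, nrow(res$deltas))
  expect_gte(res$n_genes, res$dmg$n_dmg)
})
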