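test_that("simulated genomes are deterministic and structurally valid", {
  cfg <- sim_config(genome_length = 20000L, n_chromosomes = 1L,
                    n_genes = 10L, exons_per_gene = c(2L, 4L),
                    gene_length = c(400L, 800L), seed = 1L)
  dir <- withr::local_tempdir()
  for (run in 1:2) {
    g <- simulate_genome(cfg)
    write_fasta(g$genome, file.path(dir, paste0("ref", run, ".fa")))
    write_gff3(g$models, file.path(dir, paste0("genes", run, ".gff3")))
  }
  expect_identical(readLines(file.path(dir, "ref1.fa")),
                   readLines(file.path(dir, "ref2.fa")))
  expect_identical(readLines(file.path(dir, "genes1.gff3")),
                   readLines(file.path(dir, "genes2.gff3")))

  # validate structure by re-parsing the emitted GFF3
  back <- read_gff3(file.path(dir, "genes1.gff3"))
  expect_equal(nrow(back$genes), 10L)
  per_gene <- table(back$exons$gene_id)
  expect_true(all(per_gene >= 2L & per_gene <= 4L))
  for (id in back$genes$gene_id) {
    e <- back$exons[back$exons$gene_id == id, ]
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1L] > e$end[-nrow(e)]))
  }
  # genes do not overlap
  g1 <- back$genes[order(back$genes$start), ]
  expect_true(all(g1$start[-1L] > g1$end[-nrow(g1)]))
})

test_that("a study with no genes yields sequence but an empty annotation", {
  cfg <- sim_config(genome_length = 5000L, n_chromosomes = 1L, n_genes = 0L)
  g <- simulate_genome(cfg)
  expect_equal(sum(Biostrings::width(g$genome)), 5000L)
  expect_equal(nrow(g$models$genes), 0L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g$models, path)
  expect_equal(nrow(read_gff3(path)$genes), 0L)
})

test_that("an undersized genome raises a sizing error", {
  cfg <- sim_config(genome_length = 3000L, n_chromosomes = 1L, n_genes = 10L,
                    gene_length = c(800L, 900L))
  expect_error(simulate_genome(cfg), "genome too small")
})

test_that("degenerate base rates pin methylation counts", {
  cfg0 <- sim_config(genome_length = 5000L, n_chromosomes = 1L, n_genes = 2L,
                     gene_length = c(400L, 600L),
                     base_rates = c(CpG = 0, CHG = 0, CHH = 0), seed = 5L)
  g <- simulate_genome(cfg0)
  sim0 <- simulate_methylome(cfg0, g$genome, g$models, "control")
  expect_true(all(sim0$report$meth == 0L))

  cfg1 <- sim_config(genome_length = 5000L, n_chromosomes = 1L, n_genes = 2L,
                     gene_length = c(400L, 600L), depth_mean = 50,
                     base_rates = c(CpG = 1, CHG = 1, CHH = 1), seed = 5L)
  sim1 <- simulate_methylome(cfg1, g$genome, g$models, "control")
  covered <- sim1$report$meth + sim1$report$unmeth > 0
  expect_true(any(covered))
  expect_true(all(sim1$report$unmeth[covered] == 0L))
})

test_that("identical configurations reproduce identical methylomes", {
  cfg <- sim_small(seed = 9L, effect_size = 5, affected_fraction = 0.5)
  g <- simulate_genome(cfg)
  a <- simulate_methylome(cfg, g$genome, g$models, "treated")
  b <- simulate_methylome(cfg, g$genome, g$models, "treated")
  expect_identical(a$report, b$report)
  expect_identical(a$truth$sites, b$truth$sites)
  # different conditions share baselines but not read sampling
  ctl <- simulate_methylome(cfg, g$genome, g$models, "control")
  expect_false(identical(ctl$report$meth, a$report$meth))
})

test_that("unknown condition labels are rejected", {
  cfg <- sim_small()
  g <- simulate_genome(cfg)
  expect_error(simulate_methylome(cfg, g$genome, g$models, "flood"),
               "unknown condition")
})

test_that("the imposed effect appears exactly in the truth tables", {
  # base rates far from the [0,1] bounds so the +10-point shift never clamps
  cfg <- sim_config(genome_length = 30000L, n_chromosomes = 1L,
                    n_genes = 10L, gene_length = c(600L, 1000L),
                    base_rates = c(CpG = 0.4, CHG = 0.3, CHH = 0.3),
                    effect_size = 10, affected_fraction = 1, seed = 2L)
  g <- simulate_genome(cfg)
  tr <- simulate_methylome(cfg, g$genome, g$models, "treated")$truth
  ct <- simulate_methylome(cfg, g$genome, g$models, "control")$truth
  ex <- tr$sites$region == "exonic"
  expect_identical(tr$sites$region, ct$sites$region)
  # every exonic site is shifted by exactly +10 points (clamped at 1)
  expect_equal(tr$sites$p[ex], pmin(1, ct$sites$p[ex] + 0.10))
  unclamped <- ex & ct$sites$p < 0.9
  expect_equal(mean(tr$sites$p[unclamped] - ct$sites$p[unclamped]), 0.10)
  expect_equal(tr$sites$p[!ex], ct$sites$p[!ex])
  expect_true(all(tr$genes$effect == 10))
})

test_that("the affected-gene fraction matches the configuration", {
  for (frac in c(0.25, 0.6)) {
    cfg <- sim_config(genome_length = 60000L, n_chromosomes = 2L,
                      n_genes = 20L, gene_length = c(600L, 1000L),
                      effect_size = 5, affected_fraction = frac, seed = 4L)
    g <- simulate_genome(cfg)
    tr <- simulate_methylome(cfg, g$genome, g$models, "treated")$truth
    expect_lte(abs(mean(tr$genes$affected) - frac), 1 / 20)
    expect_true(all(tr$genes$effect[tr$genes$affected] == 5))
    expect_true(all(tr$genes$effect[!tr$genes$affected] == 0))
  }
})

test_that("emitted context and region truth agree with independent scans", {
  cfg <- sim_config(genome_length = 20000L, n_chromosomes = 1L, n_genes = 8L,
                    gene_length = c(500L, 900L), n_rate = 0.005, seed = 6L)
  g <- simulate_genome(cfg)
  dir <- withr::local_tempdir()
  write_fasta(g$genome, file.path(dir, "ref.fa"))
  write_gff3(g$models, file.path(dir, "genes.gff3"))
  sim <- simulate_methylome(cfg, g$genome, g$models, "control")

  # context: classify_context re-run on the emitted FASTA
  ref <- read_fasta(file.path(dir, "ref.fa"))
  ctx <- classify_context(ref, sim$report$chrom, sim$report$pos,
                          sim$report$strand)
  expect_identical(ctx, sim$report$context)
  # and against a string-operation oracle on the raw sequence
  seq_str <- as.character(ref[["chr1"]])
  expect_identical(oracle_context(seq_str, sim$report$pos,
                                  sim$report$strand),
                   sim$report$context)

  # region truth: per-base scan of the emitted GFF3
  models <- read_gff3(file.path(dir, "genes.gff3"))
  orc <- oracle_region(models, "chr1", nchar(seq_str))
  expect_identical(orc$region[sim$truth$sites$pos], sim$truth$sites$region)
  expect_identical(orc$gene_id[sim$truth$sites$pos], sim$truth$sites$gene_id)
})

test_that("with zero effect the conditions are exchangeable", {
  meds <- vapply(1:6, function(s) {
    cfg <- sim_config(genome_length = 12000L, n_chromosomes = 1L,
                      n_genes = 10L, gene_length = c(400L, 700L),
                      effect_size = 0, affected_fraction = 1, seed = s)
    g <- simulate_genome(cfg)
    ms <- lapply(c("control", "treated"), function(cond) {
      sim <- simulate_methylome(cfg, g$genome, g$models, cond)
      cls <- classify_sites(sim$report, g$models)
      aggregate_genes(cls, g$models, cond)
    })
    d <- suppressMessages(per_gene_deltas(ms[[2L]], ms[[1L]]))
    median_shift(d)$median_diff
  }, numeric(1))
  # centred at zero across seeds
  expect_lte(abs(mean(meds)), 1)
})

test_that("simulate_study writes a complete, loadable file set", {
  cfg <- sim_config(genome_length = 20000L, n_chromosomes = 1L, n_genes = 6L,
                    gene_length = c(500L, 800L),
                    condition_effects = c(control = 0, drought = 4), seed = 8L)
  dir <- withr::local_tempdir()
  out <- simulate_study(cfg, dir)
  sheet <- read_sample_sheet(out$sample_sheet)
  expect_equal(nrow(sheet), 2L)
  expect_setequal(sheet$condition, c("control", "drought"))
  for (p in sheet$report_path)
    expect_gt(nrow(read_cytosine_report(p)), 0L)
  expect_equal(nrow(read_gff3(out$annotation)$genes), 6L)
})
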