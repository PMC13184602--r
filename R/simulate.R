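#' Configuration for the synthetic methylome generator
#'
#' Defines a desk-scale study the rest of the pipeline can be exercised on:
#' a random reference genome with non-overlapping gene models (exons,
#' introns, intergenic space), and per-condition cytosine reports whose
#' site-level methylation probabilities follow the typical plant gene-body
#' pattern — high CpG, intermediate CHG, low CHH methylation. Treatment
#' effects are additive shifts (in percentage points) applied to the
#' methylation probability of exonic sites of an affected subset of genes.
#'
#' Each site's baseline probability is drawn once (from a stream derived
#' only from `seed`), so the same site has the same baseline in every
#' condition; conditions differ by their shift and by independent read
#' sampling. Identical configurations therefore reproduce byte-identical
#' outputs, and with all effects zero the conditions are exchangeable.
#'
#' @param genome_length Total genome size in bases.
#' @param n_chromosomes Number of chromosomes (named `chr1..chrN`).
#' @param n_genes Number of genes, placed without overlap.
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param gene_length Length-2 integer range of gene span lengths (bases).
#' @param exon_fraction Fraction of a gene span covered by exons (the rest
#'   is intronic); chosen so exonic:intronic space is roughly 40:60 as in
#'   plant gene bodies.
#' @param base_rates Named vector of mean methylation fractions per context,
#'   in `[0,1]`.
#' @param rate_dispersion Beta-distribution concentration (> 0) around each
#'   context mean; smaller values give more site-to-site spread.
#' @param depth_mean Mean read depth per site (> 0).
#' @param depth_dispersion Negative-binomial size parameter; overdispersed
#'   depths put sites on both sides of the depth-5 filter.
#' @param effect_size Percentage points added to exonic site probabilities
#'   of affected genes in the `"treated"` condition (used when
#'   `condition_effects` is NULL).
#' @param affected_fraction Fraction of genes in `[0,1]` receiving the
#'   effect.
#' @param condition_effects Named numeric vector mapping condition labels to
#'   shifts in percentage points; default `c(control = 0, treated =
#'   effect_size)`.
#' @param n_samples_per_condition Reports per condition; the default 1
#'   mirrors a pooled-replicate sequencing design, values > 1 give
#'   replicated output.
#' @param n_rate Fraction of reference bases replaced by N (default 0);
#'   nonzero values exercise undeterminable-context handling.
#' @param seed Integer seed; the sole source of randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_chromosomes = 2L,
                       n_genes = 25L, exons_per_gene = c(2L, 4L),
                       gene_length = c(800L, 1600L), exon_fraction = 0.4,
                       base_rates = c(CpG = 0.80, CHG = 0.50, CHH = 0.10),
                       rate_dispersion = 5, depth_mean = 10,
                       depth_dispersion = 5, effect_size = 0,
                       affected_fraction = 0, condition_effects = NULL,
                       n_samples_per_condition = 1L, n_rate = 0, seed = 1L) {
  stopifnot(.is_count(genome_length), genome_length >= 1,
            .is_count(n_chromosomes), n_chromosomes >= 1,
            .is_count(n_genes),
            length(exons_per_gene) == 2L, all(exons_per_gene >= 1L),
            exons_per_gene[1] <= exons_per_gene[2],
            length(gene_length) == 2L, all(gene_length >= 10L),
            gene_length[1] <= gene_length[2],
            .is_fraction(exon_fraction), exon_fraction > 0,
            .is_fraction(base_rates),
            all(.CONTEXTS %in% names(base_rates)),
            is.numeric(rate_dispersion), rate_dispersion > 0,
            is.numeric(depth_mean), depth_mean > 0,
            is.numeric(depth_dispersion), depth_dispersion > 0,
            is.numeric(effect_size),
            .is_fraction(affected_fraction),
            .is_count(n_samples_per_condition), n_samples_per_condition >= 1,
            .is_fraction(n_rate),
            is.numeric(seed), length(seed) == 1L)
  if (is.null(condition_effects))
    condition_effects <- c(control = 0, treated = effect_size)
  stopifnot(is.numeric(condition_effects), !is.null(names(condition_effects)),
            all(nzchar(names(condition_effects))))
  structure(list(genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 gene_length = as.integer(gene_length),
                 exon_fraction = exon_fraction,
                 base_rates = base_rates[.CONTEXTS],
                 rate_dispersion = rate_dispersion,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 effect_size = effect_size,
                 affected_fraction = affected_fraction,
                 condition_effects = condition_effects,
                 n_samples_per_condition = as.integer(n_samples_per_condition),
                 n_rate = n_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference genome and gene models
#'
#' Generates `chr1..chrN` as random A/C/G/T sequence (GC content ~0.42,
#' optional Ns) and places the requested number of non-overlapping genes
#' with exon/intron structure, leaving intergenic space between and around
#' them. Deterministic for a given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `models` (a [gene_models()] object; empty when `n_genes = 0`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chr_len <- .rand_composition(cfg$genome_length, cfg$n_chromosomes,
                               min = max(1L, cfg$genome_length %/%
                                           (2L * cfg$n_chromosomes)))
  chr_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  probs <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)
  seqs <- vapply(chr_len, function(L) {
    b <- sample(names(probs), L, replace = TRUE, prob = probs)
    if (cfg$n_rate > 0) {
      nn <- round(cfg$n_rate * L)
      if (nn > 0) b[sample.int(L, nn)] <- "N"
    }
    paste(b, collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chr_names))

  if (cfg$n_genes == 0L) {
    models <- gene_models(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0)),
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0)))
    return(list(genome = genome, models = models))
  }

  gl <- sample(cfg$gene_length[1]:cfg$gene_length[2], cfg$n_genes,
               replace = TRUE)
  chrom_of <- ((seq_len(cfg$n_genes) - 1L) %% cfg$n_chromosomes) + 1L
  genes <- exons <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    gi <- which(chrom_of == ci)
    if (!length(gi)) next
    free <- chr_len[ci] - sum(gl[gi])
    if (free < length(gi) + 1L)
      stop("genome too small: chromosome ", chr_names[ci], " cannot hold ",
           length(gi), " genes totalling ", sum(gl[gi]),
           " bases with intergenic space")
    gaps <- .rand_composition(free, length(gi) + 1L, min = 1L)
    pos <- 0L
    for (k in seq_along(gi)) {
      gid <- gid + 1L
      start <- pos + gaps[k] + 1L
      end <- start + gl[gi[k]] - 1L
      pos <- end
      id <- sprintf("gene%04d", gid)
      genes[[gid]] <- data.frame(
        gene_id = id, chrom = chr_names[ci],
        strand = sample(c("+", "-"), 1L), start = start, end = end,
        stringsAsFactors = FALSE)
      L <- gl[gi[k]]
      k_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
      min_ex <- 30L; min_in <- 20L
      k_max <- max(1L, (L + min_in) %/% (min_ex + min_in))
      k_ex <- min(k_ex, k_max)
      if (k_ex == 1L) {
        ex_len <- L
        in_len <- integer(0)
      } else {
        ex_total <- max(k_ex * min_ex,
                        min(round(cfg$exon_fraction * L),
                            L - (k_ex - 1L) * min_in))
        ex_len <- .rand_composition(ex_total, k_ex, min = min_ex)
        in_len <- .rand_composition(L - ex_total, k_ex - 1L, min = min_in)
      }
      es <- start + c(0L, cumsum(ex_len[-k_ex] + in_len))
      exons[[gid]] <- data.frame(
        gene_id = id, chrom = chr_names[ci],
        start = es, end = es + ex_len - 1L, stringsAsFactors = FALSE)
    }
  }
  list(genome = genome,
       models = gene_models(do.call(rbind, genes), do.call(rbind, exons)))
}

# enumerate every cytosine on both strands with context/tri; NA context rows
# (Ns, contig ends) are dropped
.enumerate_cytosines <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    chars <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]]
    plus <- which(chars == "C")
    minus <- which(chars == "G")
    pos <- c(plus, minus)
    strand <- rep(c("+", "-"), c(length(plus), length(minus)))
    if (!length(pos)) return(NULL)
    cc <- .context_calls(chars, pos, strand)
    keep <- !is.na(cc$context)
    data.frame(chrom = ch, pos = pos[keep], strand = strand[keep],
               context = cc$context[keep], tri = cc$tri[keep],
               stringsAsFactors = FALSE)[order(pos[keep]), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a per-cytosine methylation report with known truth
#'
#' Every cytosine on both strands receives a site-level methylation
#' probability drawn from a beta distribution around the context's base
#' rate; exonic sites of affected genes are shifted by the condition's
#' effect (percentage points, clamped to `[0,1]`). Read depth is
#' negative-binomial and methylated counts binomial. The emitted context
#' equals the context recomputed from the reference by construction.
#'
#' @param cfg A [sim_config()].
#' @param genome,models Output of [simulate_genome()].
#' @param condition Condition label; must be a name of
#'   `cfg$condition_effects`.
#' @param replicate Replicate index (distinct read-sampling stream per
#'   replicate).
#' @return List of class `sim_methylome` with elements `report` (cytosine
#'   site data frame, see [read_cytosine_report()]) and `truth` (list with
#'   `sites`: per-site context/region/gene/probability; `genes`: per-gene
#'   applied effect; `condition`; `sample_id`).
#' @export
simulate_methylome <- function(cfg, genome, models,
                               condition = names(cfg$condition_effects)[1L],
                               replicate = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(condition %in% names(cfg$condition_effects)))
    stop("unknown condition label '", condition, "'; expected one of: ",
         paste(names(cfg$condition_effects), collapse = ", "))
  sites <- .enumerate_cytosines(genome)
  ann <- annotate_region(sites, models)
  sites$region <- ann$region
  sites$gene_id <- ann$gene_id

  n <- nrow(sites)
  gene_ids <- models$genes$gene_id
  # baseline stream: affected-gene choice and per-site baseline probability,
  # derived from cfg$seed only so every condition shares the same baselines
  set.seed(.condition_seed(cfg$seed, "baseline", 0L))
  n_aff <- round(cfg$affected_fraction * length(gene_ids))
  affected <- if (n_aff > 0) sort(sample(gene_ids, n_aff)) else character(0)
  p <- numeric(n)
  conc <- cfg$rate_dispersion
  for (ctx in .CONTEXTS) {
    idx <- which(sites$context == ctx)
    m <- cfg$base_rates[[ctx]]
    p[idx] <- if (m <= 0) 0 else if (m >= 1) 1 else
      stats::rbeta(length(idx), m * conc, (1 - m) * conc)
  }
  eff <- unname(cfg$condition_effects[condition])
  shifted <- sites$region == "exonic" & sites$gene_id %in% affected
  p[shifted] <- pmin(1, pmax(0, p[shifted] + eff / 100))

  # condition stream: read sampling only
  set.seed(.condition_seed(cfg$seed, condition, replicate))
  depth <- stats::rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean)
  meth <- stats::rbinom(n, depth, p)
  sample_id <- if (cfg$n_samples_per_condition > 1L)
    paste0(condition, "_rep", replicate) else condition

  report <- data.frame(chrom = sites$chrom, pos = sites$pos,
                       strand = sites$strand, meth = meth,
                       unmeth = depth - meth, context = sites$context,
                       tri = sites$tri, stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = gene_ids,
    affected = gene_ids %in% affected,
    effect = ifelse(gene_ids %in% affected, eff, 0),
    stringsAsFactors = FALSE)
  truth_sites <- data.frame(sites[, c("chrom", "pos", "strand", "context",
                                      "region", "gene_id")],
                            p = p, stringsAsFactors = FALSE)
  structure(list(report = report,
                 truth = list(sites = truth_sites, genes = truth_genes,
                              condition = condition, sample_id = sample_id)),
            class = "sim_methylome")
}

#' Simulate a complete study on disk
#'
#' Writes the reference FASTA, the GFF3 gene models, one cytosine report per
#' condition x replicate, per-sample truth tables, and a sample sheet, so
#' the file-based pipeline can run end to end on synthetic data.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param genotype Genotype label recorded in the sample sheet.
#' @return Invisibly, a list with paths `reference`, `annotation`,
#'   `sample_sheet`, `reports` and the in-memory `genome`/`models`.
#' @export
simulate_study <- function(cfg, dir, genotype = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(cfg)
  ref <- file.path(dir, "reference.fa")
  ann <- file.path(dir, "genes.gff3")
  write_fasta(sim$genome, ref)
  write_gff3(sim$models, ann)
  rows <- list()
  reports <- character(0)
  for (cond in names(cfg$condition_effects)) {
    for (r in seq_len(cfg$n_samples_per_condition)) {
      mm <- simulate_methylome(cfg, sim$genome, sim$models, cond, r)
      rp <- file.path(dir, paste0(mm$truth$sample_id, ".cx.tsv"))
      write_cytosine_report(mm$report, rp)
      write_table(mm$truth$sites,
                  file.path(dir, paste0(mm$truth$sample_id, ".truth_sites.tsv")))
      write_table(mm$truth$genes,
                  file.path(dir, paste0(mm$truth$sample_id, ".truth_genes.tsv")))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = mm$truth$sample_id, genotype = genotype,
        condition = cond, stage = cond, report_path = basename(rp),
        stringsAsFactors = FALSE)
      reports <- c(reports, rp)
    }
  }
  sheet <- file.path(dir, "samples.tsv")
  write_table(do.call(rbind, rows), sheet)
  invisible(list(reference = ref, annotation = ann, sample_sheet = sheet,
                 reports = reports, genome = sim$genome, models = sim$models))
}
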