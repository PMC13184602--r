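#' Aggregate classified sites to gene-level exonic methylation
#'
#' Produces one record per gene with at least one exonic depth-passing site.
#' The gene-level methylation is the read-weighted level (total methylated
#' reads / total reads over the gene's exonic sites, in percent) by default;
#' the unweighted mean of site levels is available for sensitivity analysis.
#' Sites are matched to genes by overlap with exon intervals, so a site in
#' exons of two overlapping genes contributes to both records (each record
#' is self-contained).
#'
#' @param classified Output of [classify_sites()] (depth-filtered, with
#'   `level_pct` and `intensity`).
#' @param models A [gene_models()] object.
#' @param sample_id Sample identifier recorded in each record.
#' @param weighted If FALSE, use the unweighted mean of exonic site levels
#'   instead of the read-weighted level.
#' @param cfg A [filter_config()]; `min_meth_reads` defines when a site (and
#'   hence a gene) counts as methylated.
#' @return Data frame with one row per covered gene: `gene_id`, `sample_id`,
#'   `n_exonic_sites`, `meth_reads_sum`, `total_reads_sum`, `level_pct`,
#'   `n_cpg`, `n_chg`, `n_chh`, `n_hyper_positions`, `is_methylated_gene`.
#' @export
aggregate_genes <- function(classified, models, sample_id,
                            weighted = TRUE, cfg = filter_config()) {
  empty <- data.frame(gene_id = character(0), sample_id = character(0),
                      n_exonic_sites = integer(0), meth_reads_sum = integer(0),
                      total_reads_sum = integer(0), level_pct = numeric(0),
                      n_cpg = integer(0), n_chg = integer(0),
                      n_chh = integer(0), n_hyper_positions = integer(0),
                      is_methylated_gene = logical(0))
  if (!nrow(classified) || !nrow(models$exons)) return(empty)
  q <- GenomicRanges::GRanges(classified$chrom,
                              IRanges::IRanges(classified$pos, classified$pos))
  egr <- GenomicRanges::GRanges(models$exons$chrom,
                                IRanges::IRanges(models$exons$start,
                                                 models$exons$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, egr))
  if (!length(ov)) return(empty)
  si <- S4Vectors::queryHits(ov)
  gene <- models$exons$gene_id[S4Vectors::subjectHits(ov)]
  # a site can overlap two exons of the same gene only if exons overlap,
  # which gene_models() forbids; dedupe (site, gene) pairs defensively
  dup <- duplicated(paste(si, gene))
  si <- si[!dup]; gene <- gene[!dup]

  depth <- classified$meth[si] + classified$unmeth[si]
  mat <- cbind(n = 1L,
               meth = classified$meth[si],
               total = depth,
               cpg = as.integer(classified$context[si] == "CpG"),
               chg = as.integer(classified$context[si] == "CHG"),
               chh = as.integer(classified$context[si] == "CHH"),
               hyper = as.integer(classified$intensity[si] == "hypermethylated"),
               is_meth = as.integer(classified$meth[si] >= cfg$min_meth_reads),
               lvl = classified$level_pct[si])
  agg <- rowsum(mat, gene)
  level <- if (weighted) {
    ifelse(agg[, "total"] > 0, 100 * agg[, "meth"] / agg[, "total"], NA_real_)
  } else {
    agg[, "lvl"] / agg[, "n"]
  }
  out <- data.frame(gene_id = rownames(agg), sample_id = sample_id,
                    n_exonic_sites = as.integer(agg[, "n"]),
                    meth_reads_sum = as.integer(agg[, "meth"]),
                    total_reads_sum = as.integer(agg[, "total"]),
                    level_pct = level,
                    n_cpg = as.integer(agg[, "cpg"]),
                    n_chg = as.integer(agg[, "chg"]),
                    n_chh = as.integer(agg[, "chh"]),
                    n_hyper_positions = as.integer(agg[, "hyper"]),
                    is_methylated_gene = agg[, "is_meth"] > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count methylated genes in a sample
#'
#' A gene is methylated when at least one of its exonic depth-passing sites
#' carries a methylated read.
#'
#' @param records Output of [aggregate_genes()].
#' @return Integer count.
#' @export
count_methylated_genes <- function(records) {
  sum(records$is_methylated_gene)
}

#' Chromosome-wise counts of hypermethylated exonic positions
#'
#' Counts exonic sites with hypermethylated intensity (level >= 70 percent
#' under the default thresholds) per chromosome and sequence context — the
#' observational units for the ANOVA / Fisher's LSD comparison of
#' conditions.
#'
#' @param classified Output of [classify_sites()].
#' @param sample_id Sample identifier recorded in each row.
#' @return Data frame with columns `sample_id`, `chrom`, `context`,
#'   `n_hyper_exonic`, complete over every chromosome x context combination
#'   observed in `classified` (zeros included).
#' @export
chrom_context_counts <- function(classified, sample_id) {
  chroms <- sort(unique(classified$chrom))
  grid <- expand.grid(chrom = chroms, context = .CONTEXTS,
                      stringsAsFactors = FALSE)
  hyper <- classified[classified$region == "exonic" &
                        classified$intensity == "hypermethylated", ,
                      drop = FALSE]
  key <- paste(grid$chrom, grid$context)
  cnt <- table(factor(paste(hyper$chrom, hyper$context), levels = key))
  data.frame(sample_id = sample_id, chrom = grid$chrom,
             context = grid$context, n_hyper_exonic = as.integer(cnt),
             stringsAsFactors = FALSE)
}
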