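#' Specification of a condition contrast
#'
#' Pairs a test condition with its reference (mother plant for tissue
#' culture, control for drought), the significance level, the FDR method
#' and the differentially-methylated-gene (DMG) threshold.
#'
#' @param test_condition Label of the test condition.
#' @param reference_condition Label of the reference condition.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param dmg_delta_threshold Absolute gene-level methylation difference (in
#'   percentage points) from which a gene is called a DMG, default 10.
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()],
#'   default Benjamini-Hochberg (`"BH"`).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(test_condition, reference_condition,
                          alpha = 0.05, dmg_delta_threshold = 10,
                          fdr_method = "BH") {
  stopifnot(is.character(test_condition), is.character(reference_condition),
            nzchar(test_condition), nzchar(reference_condition),
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(dmg_delta_threshold), dmg_delta_threshold >= 0)
  if (test_condition == reference_condition)
    stop("test and reference condition must differ")
  structure(list(test_condition = test_condition,
                 reference_condition = reference_condition,
                 alpha = alpha,
                 dmg_delta_threshold = dmg_delta_threshold,
                 fdr_method = fdr_method),
            class = "contrast_spec")
}

#' Per-gene methylation differences between two samples
#'
#' The gene universe is the set of genes methylated in at least one of the
#' two conditions, restricted to genes with depth-passing exonic coverage in
#' both (genes covered in only one condition are dropped, with the count
#' reported via a message). Delta is `level_pct(test) - level_pct(reference)`
#' in percentage points.
#'
#' @param records_test,records_ref Outputs of [aggregate_genes()] over the
#'   same gene models.
#' @param spec A [contrast_spec()] (used for labelling only here).
#' @return Data frame with columns `gene_id`, `level_test`, `level_ref`,
#'   `delta`.
#' @export
per_gene_deltas <- function(records_test, records_ref, spec = NULL) {
  m <- merge(records_test[, c("gene_id", "level_pct", "is_methylated_gene")],
             records_ref[, c("gene_id", "level_pct", "is_methylated_gene")],
             by = "gene_id", suffixes = c("_test", "_ref"))
  n_dropped <- length(union(records_test$gene_id, records_ref$gene_id)) - nrow(m)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) without coverage in both conditions dropped")
  m <- m[m$is_methylated_gene_test | m$is_methylated_gene_ref, , drop = FALSE]
  if (!nrow(m))
    stop("empty gene universe: no gene methylated in either condition")
  out <- data.frame(gene_id = m$gene_id,
                    level_test = m$level_pct_test,
                    level_ref = m$level_pct_ref,
                    delta = m$level_pct_test - m$level_pct_ref,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide methylation shift and across-loci variability
#'
#' The median of per-gene deltas is the genome-wide effect size (sign =
#' direction of the shift); the standard deviation of the deltas (n-1
#' denominator) measures variability across loci. For an even number of
#' genes the median is the mean of the two central order statistics.
#'
#' @param deltas Numeric vector of per-gene deltas, or the data frame from
#'   [per_gene_deltas()].
#' @return List with `median_diff` and `sd_loci`.
#' @export
median_shift <- function(deltas) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  stopifnot(is.numeric(deltas), length(deltas) >= 1L)
  list(median_diff = stats::median(deltas),
       sd_loci = if (length(deltas) > 1L) stats::sd(deltas) else NA_real_)
}

#' Paired Wilcoxon signed-rank tests with BH correction across stages
#'
#' Applies a two-sided paired Wilcoxon signed-rank test to the per-gene
#' deltas of every stage in a contrast family (e.g. each subculture stage
#' against the mother plant) and adjusts the resulting p-values with
#' Benjamini-Hochberg across the family. Zero deltas are dropped before
#' ranking (Wilcoxon's original treatment); the exact distribution is used
#' for n <= 25 without ties, the normal approximation with continuity
#' correction otherwise. If every delta of a stage is zero the test is
#' degenerate and p is reported as 1.
#'
#' @param delta_tables Named list; each element a numeric vector of deltas
#'   or a [per_gene_deltas()] data frame, one per stage.
#' @param spec A [contrast_spec()] supplying `alpha` and `fdr_method`.
#' @return Data frame with one row per stage: `stage`, `n_genes`,
#'   `n_nonzero`, `statistic`, `p_value`, `q_value`, `degenerate`,
#'   `significant`.
#' @export
wilcoxon_bh <- function(delta_tables, spec = contrast_spec("test", "ref")) {
  stopifnot(is.list(delta_tables), length(delta_tables) >= 1L)
  if (is.null(names(delta_tables)) || !all(nzchar(names(delta_tables))))
    names(delta_tables) <- paste0("stage", seq_along(delta_tables))
  one <- function(d) {
    if (is.data.frame(d)) d <- d$delta
    nz <- d[d != 0]
    if (!length(nz))
      return(data.frame(n_genes = length(d), n_nonzero = 0L,
                        statistic = NA_real_, p_value = 1,
                        degenerate = TRUE))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                         exact = length(nz) <= 25L, correct = TRUE))
    data.frame(n_genes = length(d), n_nonzero = length(nz),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               degenerate = FALSE)
  }
  out <- do.call(rbind, lapply(delta_tables, one))
  out <- cbind(stage = names(delta_tables), out)
  out$q_value <- stats::p.adjust(out$p_value, method = spec$fdr_method)
  out$significant <- out$q_value < spec$alpha
  rownames(out) <- NULL
  out
}

#' Call differentially methylated genes
#'
#' Genes whose absolute gene-level methylation difference meets the
#' threshold are DMGs. The count is also reported normalised "per 100
#' points" of the observed absolute-delta range, for comparability between
#' genotypes with different dynamic ranges.
#'
#' @param deltas A [per_gene_deltas()] data frame (or numeric vector with
#'   names as gene ids).
#' @param spec A [contrast_spec()] supplying `dmg_delta_threshold`.
#' @return List with `dmg_ids`, `n_dmg`, `n_genes`, `threshold`,
#'   `dmg_per_100_points` (`NA` when the observed range is zero).
#' @export
call_dmgs <- function(deltas, spec = contrast_spec("test", "ref")) {
  if (is.numeric(deltas))
    deltas <- data.frame(gene_id = if (is.null(names(deltas)))
      as.character(seq_along(deltas)) else names(deltas), delta = deltas)
  hit <- abs(deltas$delta) >= spec$dmg_delta_threshold &
    (spec$dmg_delta_threshold > 0 | deltas$delta != 0)
  rng <- diff(range(abs(deltas$delta)))
  list(dmg_ids = deltas$gene_id[hit],
       n_dmg = sum(hit),
       n_genes = nrow(deltas),
       threshold = spec$dmg_delta_threshold,
       dmg_per_100_points = if (rng > 0) sum(hit) / (rng / 100) else NA_real_)
}

#' Full contrast of one test sample against a reference
#'
#' Runs [per_gene_deltas()], [median_shift()], the paired Wilcoxon test,
#' [call_dmgs()] and the percent change in methylated-gene counts for one
#' test/reference pair. For a family of stages sharing one BH correction,
#' run [per_gene_deltas()] per stage and [wilcoxon_bh()] on the family
#' instead; here the single p-value is its own family.
#'
#' @param records_test,records_ref Outputs of [aggregate_genes()].
#' @param spec A [contrast_spec()].
#' @return Object of class `meth_contrast`: list with `spec`, `deltas`,
#'   `n_genes`, `median_diff`, `sd_loci`, `wilcoxon` (one-row data frame),
#'   `dmg`, `n_methylated_test`, `n_methylated_ref`,
#'   `pct_change_methylated_genes`.
#' @export
contrast_genes <- function(records_test, records_ref, spec) {
  stopifnot(inherits(spec, "contrast_spec"))
  deltas <- per_gene_deltas(records_test, records_ref, spec)
  ms <- median_shift(deltas)
  wt <- wilcoxon_bh(stats::setNames(list(deltas), spec$test_condition), spec)
  dmg <- call_dmgs(deltas, spec)
  n_ref <- count_methylated_genes(records_ref)
  n_test <- count_methylated_genes(records_test)
  structure(list(spec = spec, deltas = deltas, n_genes = nrow(deltas),
                 median_diff = ms$median_diff, sd_loci = ms$sd_loci,
                 wilcoxon = wt, dmg = dmg,
                 n_methylated_test = n_test, n_methylated_ref = n_ref,
                 pct_change_methylated_genes =
                   if (n_ref > 0) percent_change(n_ref, n_test) else NA_real_),
            class = "meth_contrast")
}

#' @export
print.meth_contrast <- function(x, ...) {
  cat(sprintf("Contrast: %s vs %s (reference)\n", x$spec$test_condition,
              x$spec$reference_condition))
  cat(sprintf("  genes in universe: %d\n", x$n_genes))
  cat(sprintf("  median shift: %+.2f points (sd across loci %.2f)\n",
              x$median_diff, x$sd_loci))
  cat(sprintf("  Wilcoxon signed-rank p = %.4g, BH q = %.4g%s\n",
              x$wilcoxon$p_value, x$wilcoxon$q_value,
              if (x$wilcoxon$degenerate) " (degenerate: all deltas zero)" else ""))
  cat(sprintf("  DMGs (|delta| >= %g): %d\n", x$spec$dmg_delta_threshold,
              x$dmg$n_dmg))
  cat(sprintf("  methylated genes: %d (test) vs %d (ref), change %+.2f%%\n",
              x$n_methylated_test, x$n_methylated_ref,
              x$pct_change_methylated_genes))
  invisible(x)
}

# p-value matrix of pairwise Fisher's LSD comparisons given group means,
# sizes and the pooled ANOVA error
.lsd_pairwise_p <- function(means, ns, mse, df) {
  k <- length(means)
  p <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (mse <= 0) {
      pij <- if (means[i] == means[j]) 1 else 0
    } else {
      tstat <- abs(means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      pij <- 2 * stats::pt(-tstat, df)
    }
    p[i, j] <- p[j, i] <- pij
  }
  p
}

# compact letter display from a logical "not significantly different"
# matrix: one letter per maximal all-NSD subset (exact enumeration; group
# counts here are small)
.compact_letters <- function(nsd) {
  k <- nrow(nsd)
  if (k == 1L) return(stats::setNames("a", rownames(nsd)))
  subsets <- list()
  for (code in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (all(nsd[idx, idx])) subsets[[length(subsets) + 1L]] <- idx
  }
  sizes <- vapply(subsets, length, integer(1))
  maximal <- subsets[vapply(seq_along(subsets), function(i) {
    !any(vapply(subsets, function(s)
      length(s) > sizes[i] && all(subsets[[i]] %in% s), logical(1)))
  }, logical(1))]
  ord <- order(vapply(maximal, min, integer(1)))
  maximal <- maximal[ord]
  letts <- character(k)
  for (i in seq_along(maximal))
    letts[maximal[[i]]] <- paste0(letts[maximal[[i]]], letters[i])
  stats::setNames(letts, rownames(nsd))
}

#' One-way ANOVA with Fisher's LSD letter groups
#'
#' Tests whether chromosome-wise counts of hypermethylated exonic positions
#' differ between condition x context groups, treating chromosomes as
#' replicates within each group. When the ANOVA is significant at `alpha`,
#' pairwise comparisons with Fisher's least significant difference (the
#' pooled-error t-test, no further adjustment) produce a compact letter
#' display: groups sharing a letter do not differ at `alpha`. A
#' non-significant ANOVA yields a single shared letter. With zero residual
#' variance the F statistic is infinite (p reported as 0) and any mean
#' difference separates groups.
#'
#' @param counts Data frame as from [chrom_context_counts()], with columns
#'   `n_hyper_exonic` plus grouping columns; rows from several samples are
#'   combined by their `sample_id`.
#' @param grouping Character vector of column names whose interaction
#'   defines the groups (default `c("sample_id", "context")`, i.e.
#'   condition x context).
#' @param alpha Significance level, default 0.05.
#' @return Object of class `meth_lsd`: list with `f_statistic`, `p_value`,
#'   `df`, `mse`, `anova_significant` and `groups` (data frame of group,
#'   n, mean and letter).
#' @export
anova_lsd <- function(counts, grouping = c("sample_id", "context"),
                      alpha = 0.05) {
  stopifnot("n_hyper_exonic" %in% names(counts),
            all(grouping %in% names(counts)))
  grp <- interaction(counts[grouping], sep = ":", drop = TRUE)
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(grp) %in% small)
    counts <- counts[keep, , drop = FALSE]
    grp <- droplevels(grp[keep])
  }
  if (nlevels(grp) < 2L)
    stop("ANOVA needs at least 2 groups with >= 2 observations each")
  y <- counts$n_hyper_exonic
  fit <- stats::aov(y ~ grp)
  # degenerate (zero-variance) fits are handled explicitly below
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mse <- an[["Mean Sq"]][2L]
  df <- an[["Df"]][2L]
  msg <- an[["Mean Sq"]][1L]
  # exactly constant data leave floating-point dust in the mean squares
  scale_tol <- 1e-10 * (mean(y)^2 + 1)
  if (msg <= scale_tol) msg <- 0
  if (mse <= scale_tol) mse <- 0
  if (mse <= 0) {
    f <- if (msg > 0) Inf else NaN
    p <- if (msg > 0) 0 else NA_real_
  } else {
    f <- an[["F value"]][1L]
    p <- an[["Pr(>F)"]][1L]
  }
  means <- tapply(y, grp, mean)
  ns <- as.integer(table(grp))
  names(ns) <- names(means)
  if (!is.na(p) && p < alpha) {
    pw <- .lsd_pairwise_p(means, ns, mse, df)
    letts <- .compact_letters(pw >= alpha)
  } else {
    pw <- NULL
    letts <- stats::setNames(rep("a", length(means)), names(means))
  }
  groups <- data.frame(group = names(means), n = ns, mean = as.numeric(means),
                       letter = letts[names(means)], stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(f_statistic = f, p_value = p, df = df, mse = mse,
                 anova_significant = !is.na(p) && p < alpha,
                 pairwise_p = pw, alpha = alpha, groups = groups),
            class = "meth_lsd")
}

#' @export
print.meth_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %s on %d residual df, p = %s\n",
              format(x$f_statistic), x$df, format(x$p_value)))
  cat("Fisher's LSD letter groups (alpha =", x$alpha, "):\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Variability of methylated-gene counts across stages
#'
#' Standard deviation (n-1 denominator) of per-stage methylated-gene counts
#' relative to a common baseline grouping — the summary used to compare the
#' stability of propagation methods.
#'
#' @param counts Numeric vector of methylated-gene counts, one per stage.
#' @return Standard deviation; `NA` with a warning for fewer than 2 values.
#' @export
variability_across_stages <- function(counts) {
  stopifnot(is.numeric(counts))
  if (length(counts) < 2L) {
    warning("fewer than 2 stage counts; SD undefined")
    return(NA_real_)
  }
  stats::sd(counts)
}
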