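#' Build a feature x sample methylation matrix
#'
#' Assembles gene-level (or exon-level) methylation percentages from several
#' samples into one matrix, keeping only complete cases: features with a
#' defined level in every sample (no imputation).
#'
#' @param records_list Named list of [aggregate_genes()] outputs, one per
#'   sample; names become column names.
#' @return Numeric matrix, rows = features (gene ids), columns = samples.
#' @export
methylation_matrix <- function(records_list) {
  stopifnot(is.list(records_list), length(records_list) >= 1L,
            !is.null(names(records_list)))
  common <- Reduce(intersect, lapply(records_list, function(r) r$gene_id))
  common <- sort(common)
  mat <- vapply(records_list, function(r) {
    r$level_pct[match(common, r$gene_id)]
  }, numeric(length(common)))
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(common, names(records_list)))
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' Keep the k most variable features
#'
#' Ranks features by their across-sample variance (n-1 denominator) and
#' retains the top k; ties are broken by feature identifier order. Used to
#' focus the PCA on the most informative exons/genes.
#'
#' @param mat Feature x sample matrix.
#' @param k Number of features to keep; clipped with a warning when larger
#'   than the number of features.
#' @return The reduced matrix (row order: decreasing variance).
#' @export
top_k_variable <- function(mat, k) {
  stopifnot(is.matrix(mat), .is_count(k))
  if (k > nrow(mat)) {
    warning("k = ", k, " exceeds ", nrow(mat), " features; keeping all")
    k <- nrow(mat)
  }
  v <- apply(mat, 1L, stats::var)
  ord <- order(-v, rownames(mat))
  mat[ord[seq_len(k)], , drop = FALSE]
}

#' Principal component analysis of samples in methylation space
#'
#' PCA of the samples on centred (by default unscaled — all features share
#' percentage units) methylation levels. Components are ordered by
#' non-increasing explained variance.
#'
#' @param mat Feature x sample matrix (e.g. after [top_k_variable()]).
#' @param scale. Scale features to unit variance before the PCA (default
#'   FALSE).
#' @return Object of class `meth_pca` (or `NULL`, with a message, when the
#'   matrix has no variance): list with `scores` (samples x PCs),
#'   `loadings` (features x PCs), `var_explained` (fractions summing to 1)
#'   and the underlying `prcomp` fit.
#' @export
methyl_pca <- function(mat, scale. = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  x <- t(mat)
  if (all(apply(x, 2L, stats::var) == 0)) {
    message("constant matrix: zero variance, PCA skipped")
    return(NULL)
  }
  if (scale.) {
    keep <- apply(x, 2L, stats::var) > 0
    x <- x[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 var_explained = ve, fit = fit), class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  k <- min(5L, length(x$var_explained))
  cat("PCA of", nrow(x$scores), "samples on", nrow(x$loadings), "features\n")
  cat("  variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of common hypermethylated genes
#'
#' Restricts the gene set to genes whose gene-level methylation is
#' hypermethylated (>= `hyper_min_pct`) in every sample, then clusters the
#' samples agglomeratively on that matrix (Euclidean distance, average
#' linkage by default). The dendrogram is deterministic for a fixed input
#' order and exportable as Newick.
#'
#' @param records_list Named list of [aggregate_genes()] outputs.
#' @param hyper_min_pct Gene-level hypermethylation threshold in percent.
#' @param dist_method Distance passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `meth_hclust` (or `NULL`, with a message, when
#'   the common hypermethylated set is empty): list with `hclust`,
#'   `common_genes`, `matrix` and `newick`.
#' @export
cluster_common_hyper <- function(records_list, hyper_min_pct = 70,
                                 dist_method = "euclidean",
                                 linkage = "average") {
  mat <- methylation_matrix(records_list)
  common <- rownames(mat)[apply(mat >= hyper_min_pct, 1L, all)]
  if (!length(common)) {
    message("no gene hypermethylated in every sample; clustering skipped")
    return(NULL)
  }
  m <- mat[common, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m), method = dist_method),
                      method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, common_genes = common, matrix = m,
                 newick = nwk), class = "meth_hclust")
}

#' @export
print.meth_hclust <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$common_genes),
      "common hypermethylated genes across", ncol(x$matrix), "samples\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Multi-set overlap (Venn) counts
#'
#' Full inclusion-exclusion decomposition of 2 or 3 labelled sets into
#' disjoint regions (unique to each set, each pairwise-only intersection,
#' common to all); the region counts partition the union. For more than 3
#' sets, a report is returned for every pair and triple.
#'
#' @param sets Named list of 2 or more character vectors (e.g. methylated
#'   gene ids per condition).
#' @return For 2-3 sets, an object of class `overlap_report`: list with
#'   `labels`, `regions` (named integer vector of disjoint region counts),
#'   `union_size`, `set_sizes`, `common_all`. For > 3 sets, a list of
#'   `overlap_report`s named by the combination.
#' @export
overlap_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  if (length(sets) > 3L) {
    combos <- c(utils::combn(length(sets), 2L, simplify = FALSE),
                utils::combn(length(sets), 3L, simplify = FALSE))
    out <- lapply(combos, function(i) overlap_counts(sets[i]))
    names(out) <- vapply(combos, function(i)
      paste(names(sets)[i], collapse = "&"), character(1))
    return(out)
  }
  labs <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, labs))
  sig <- apply(member, 1L, function(r) paste(labs[r], collapse = "&"))
  all_sigs <- unlist(lapply(seq_along(labs), function(k)
    utils::combn(labs, k, paste, collapse = "&")))
  regions <- table(factor(sig, levels = all_sigs))
  structure(list(labels = labs,
                 regions = stats::setNames(as.integer(regions), all_sigs),
                 union_size = length(universe),
                 set_sizes = vapply(sets, length, integer(1)),
                 common_all = sum(Reduce(`&`, asplit(member, 2L)))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap of", length(x$labels), "sets (union:", x$union_size, ")\n")
  for (nm in names(x$regions))
    cat(sprintf("  %-30s %d\n", nm, x$regions[[nm]]))
  invisible(x)
}
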