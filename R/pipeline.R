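#' Configuration of a full pipeline run
#'
#' Bundles everything one reproducible run needs: either a [sim_config()]
#' (inputs are generated) or paths to an existing reference, annotation and
#' sample sheet; the site filter; the contrasts to compute; pattern-layer
#' options; a seed and a log level.
#'
#' @param out_dir Output directory.
#' @param simulate Optional [sim_config()]; when given, inputs are
#'   simulated into `out_dir/sim` and the path arguments are ignored.
#' @param reference,annotation,sample_sheet Paths to FASTA, GFF3 and the
#'   sample sheet (required when `simulate` is NULL).
#' @param filter A [filter_config()].
#' @param contrasts List of [contrast_spec()]s; conditions are matched
#'   against the sample sheet's `condition` column.
#' @param top_k Number of most-variable features retained for the PCA.
#' @param seed Integer seed recorded in the manifest.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, reference = NULL,
                       annotation = NULL, sample_sheet = NULL,
                       filter = filter_config(), contrasts = list(),
                       top_k = 500L, seed = 1L, log_level = "info") {
  structure(list(out_dir = out_dir, simulate = simulate,
                 reference = reference, annotation = annotation,
                 sample_sheet = sample_sheet, filter = filter,
                 contrasts = contrasts, top_k = top_k,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every invariant and returns all violations at once rather than
#' failing at the first.
#'
#' @param cfg A [run_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  if (!inherits(cfg, "run_config")) return("not a run_config object")
  if (!is.character(cfg$out_dir) || !nzchar(cfg$out_dir))
    note("out_dir must be a non-empty path")
  if (is.null(cfg$simulate)) {
    for (f in c("reference", "annotation", "sample_sheet")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        note(paste0(f, " path missing or not found: ",
                    if (is.null(cfg[[f]])) "NULL" else cfg[[f]]))
    }
    conds <- if (!is.null(cfg$sample_sheet) && file.exists(cfg$sample_sheet))
      tryCatch(read_sample_sheet(cfg$sample_sheet, check_paths = FALSE)$condition,
               error = function(e) { note(conditionMessage(e)); NULL })
    else NULL
  } else {
    if (!inherits(cfg$simulate, "sim_config"))
      note("simulate must be a sim_config")
    conds <- names(cfg$simulate$condition_effects)
  }
  if (!inherits(cfg$filter, "filter_config"))
    note("filter must be a filter_config")
  else if (!(0 < cfg$filter$hypo_max_pct &&
             cfg$filter$hypo_max_pct < cfg$filter$hyper_min_pct &&
             cfg$filter$hyper_min_pct <= 100))
    note("intensity thresholds out of order")
  for (cs in cfg$contrasts) {
    if (!inherits(cs, "contrast_spec")) { note("contrast is not a contrast_spec"); next }
    if (!(cs$alpha > 0 && cs$alpha < 1))
      note(paste0("alpha out of (0,1) in contrast ", cs$test_condition))
    if (!is.null(conds)) {
      for (lab in c(cs$test_condition, cs$reference_condition))
        if (!(lab %in% conds))
          note(paste0("condition '", lab, "' not present in the study"))
    }
  }
  bad
}

.log <- function(cfg, level, ..., logfile = NULL) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  want <- levels[[match.arg(level, names(levels))]]
  have <- levels[[cfg$log_level]]
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  if (have >= want && want > 0L) message(msg)
  invisible(NULL)
}

#' Run the full methylation pipeline
#'
#' Executes the stages in dependency order — (optional) simulation, per-
#' sample classification and summary, gene-level aggregation, contrasts,
#' pattern discovery — writing each stage's tables under `out_dir` and a
#' run manifest (tool version, config echo, per-file checksums, timestamps,
#' warning count) last. A failure in one contrast is logged and does not
#' abort the others; validation errors are reported before any computation.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `manifest_path`, `checksums` (named md5
#'   vector over output files), `summaries`, `gene_records`, `contrasts`,
#'   `patterns`.
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  cat("", file = logfile)
  n_warn <- 0L
  wh <- function(w) { n_warn <<- n_warn + 1L
    .log(cfg, "info", "warning: ", conditionMessage(w), logfile = logfile)
    invokeRestart("muffleWarning") }

  if (!is.null(cfg$simulate)) {
    .log(cfg, "info", "simulating study inputs", logfile = logfile)
    sim <- simulate_study(cfg$simulate, file.path(cfg$out_dir, "sim"))
    reference <- sim$reference; annotation <- sim$annotation
    sheet_path <- sim$sample_sheet
  } else {
    reference <- cfg$reference; annotation <- cfg$annotation
    sheet_path <- cfg$sample_sheet
  }
  genome <- read_fasta(reference)
  models <- read_gff3(annotation)
  sheet <- read_sample_sheet(sheet_path)

  summaries <- list(); gene_records <- list(); chrom_counts <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    .log(cfg, "info", "classifying sample ", sid, logfile = logfile)
    sites <- read_cytosine_report(sheet$report_path[i])
    cls <- withCallingHandlers(
      classify_sites(sites, models, cfg$filter, genome = genome),
      warning = wh)
    summaries[[sid]] <- summarize_methylation(cls, cfg$filter)
    write_table(summary_table(summaries[[sid]]),
                file.path(cfg$out_dir, paste0(sid, ".summary.tsv")))
    gene_records[[sid]] <- aggregate_genes(cls, models, sid, cfg = cfg$filter)
    write_table(gene_records[[sid]],
                file.path(cfg$out_dir, paste0(sid, ".genes.tsv")))
    chrom_counts[[sid]] <- chrom_context_counts(cls, sid)
  }
  write_table(do.call(rbind, chrom_counts),
              file.path(cfg$out_dir, "chrom_context_counts.tsv"))

  by_condition <- split(sheet$sample_id, sheet$condition)
  first_of <- function(cond) gene_records[[by_condition[[cond]][1L]]]
  contrasts <- list(); summary_rows <- list()
  for (cs in cfg$contrasts) {
    key <- paste0(cs$test_condition, "_vs_", cs$reference_condition)
    .log(cfg, "info", "contrast ", key, logfile = logfile)
    res <- tryCatch(
      withCallingHandlers(
        contrast_genes(first_of(cs$test_condition),
                       first_of(cs$reference_condition), cs),
        warning = wh),
      error = function(e) {
        .log(cfg, "info", "contrast ", key, " failed: ",
             conditionMessage(e), logfile = logfile)
        NULL
      })
    if (is.null(res)) next
    contrasts[[key]] <- res
    write_table(res$deltas, file.path(cfg$out_dir, paste0(key, ".deltas.tsv")))
    summary_rows[[key]] <- data.frame(
      contrast = key, n_genes = res$n_genes, median_diff = res$median_diff,
      sd_loci = res$sd_loci, p_value = res$wilcoxon$p_value,
      q_value = res$wilcoxon$q_value, n_dmg = res$dmg$n_dmg,
      pct_change_methylated_genes = res$pct_change_methylated_genes,
      stringsAsFactors = FALSE)
  }
  if (length(summary_rows))
    write_table(do.call(rbind, summary_rows),
                file.path(cfg$out_dir, "contrast_summary.tsv"))

  patterns <- list()
  if (length(gene_records) >= 2L) {
    mat <- methylation_matrix(gene_records)
    if (nrow(mat)) {
      red <- withCallingHandlers(
        top_k_variable(mat, min(cfg$top_k, nrow(mat))), warning = wh)
      patterns$pca <- methyl_pca(red)
      if (!is.null(patterns$pca)) {
        write_table(data.frame(sample_id = rownames(patterns$pca$scores),
                               patterns$pca$scores),
                    file.path(cfg$out_dir, "pca_scores.tsv"))
        write_table(data.frame(component = paste0("PC", seq_along(patterns$pca$var_explained)),
                               var_explained = patterns$pca$var_explained),
                    file.path(cfg$out_dir, "pca_variance.tsv"))
      }
      patterns$clustering <- cluster_common_hyper(gene_records)
      if (!is.null(patterns$clustering))
        writeLines(patterns$clustering$newick,
                   file.path(cfg$out_dir, "dendrogram.nwk"))
    }
    meth_sets <- lapply(gene_records, function(r)
      r$gene_id[r$is_methylated_gene])
    if (length(meth_sets) %in% 2:3) {
      patterns$overlap <- overlap_counts(meth_sets)
      write_table(data.frame(region = names(patterns$overlap$regions),
                             count = patterns$overlap$regions),
                  file.path(cfg$out_dir, "overlap_counts.tsv"))
    }
  }

  outputs <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE,
                                     full.names = TRUE),
                          c(file.path(cfg$out_dir, "run.log"),
                            file.path(cfg$out_dir, "manifest.txt"))))
  sums <- tools::md5sum(outputs)
  names(sums) <- sub(paste0("^", cfg$out_dir, "/?"), "", names(sums))
  manifest_path <- file.path(cfg$out_dir, "manifest.txt")
  lines <- c(
    paste0("tool_version\t", as.character(utils::packageVersion("gbmeth"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed\t", cfg$seed),
    paste0("warnings\t", n_warn),
    paste0("config\t", paste(deparse(cfg[setdiff(names(cfg), "simulate")],
                                     width.cutoff = 500L), collapse = " ")),
    paste0("checksum\t", names(sums), "\t", unname(sums)))
  writeLines(lines, manifest_path)
  .log(cfg, "info", "manifest written to ", manifest_path, logfile = logfile)
  invisible(list(manifest_path = manifest_path, checksums = sums,
                 summaries = summaries, gene_records = gene_records,
                 contrasts = contrasts, patterns = patterns,
                 n_warnings = n_warn))
}
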