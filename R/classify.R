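#' Site filtering and classification settings
#'
#' Holds the depth filter and the fixed intensity thresholds used to label
#' cytosine sites: sites need a minimum read depth of 5 by default, and a
#' site's methylation level (percent) is called hypomethylated when <= 30,
#' hypermethylated when >= 70, and intermediate strictly in between.
#'
#' @param min_depth Minimum read depth for a site to pass (default 5,
#'   boundary inclusive: depth 5 passes).
#' @param require_both_strands If TRUE, a CpG or CHG site additionally
#'   requires its strand-symmetric partner position to pass `min_depth`.
#'   CHH sites have no symmetric partner and are filtered on their own depth
#'   only. Default FALSE (plain per-site depth).
#' @param hypo_max_pct Upper bound (inclusive) of the hypomethylated bin.
#' @param hyper_min_pct Lower bound (inclusive) of the hypermethylated bin.
#' @param min_meth_reads Minimum methylated-read count for a site to count
#'   as "methylated" in summaries and gene records (default 1).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5L, require_both_strands = FALSE,
                          hypo_max_pct = 30, hyper_min_pct = 70,
                          min_meth_reads = 1L) {
  stopifnot(.is_count(min_depth), min_depth >= 1,
            is.logical(require_both_strands),
            is.numeric(hypo_max_pct), is.numeric(hyper_min_pct),
            .is_count(min_meth_reads))
  if (!(0 < hypo_max_pct && hypo_max_pct < hyper_min_pct && hyper_min_pct <= 100))
    stop("intensity thresholds must satisfy 0 < hypo_max_pct < hyper_min_pct <= 100")
  structure(list(min_depth = as.integer(min_depth),
                 require_both_strands = require_both_strands,
                 hypo_max_pct = hypo_max_pct,
                 hyper_min_pct = hyper_min_pct,
                 min_meth_reads = as.integer(min_meth_reads)),
            class = "filter_config")
}

#' Depth-filter cytosine sites
#'
#' A site survives iff its depth (`meth + unmeth`) is at least
#' `cfg$min_depth`. With `require_both_strands = TRUE`, CpG and CHG sites
#' additionally require the symmetric position on the opposite strand
#' (CpG: +1/-1 bp; CHG: +2/-2 bp) to be present and pass the depth cutoff.
#'
#' @param sites Cytosine site data frame (see [read_cytosine_report()]).
#' @param cfg A [filter_config()].
#' @return The surviving subset of `sites`.
#' @export
depth_filter <- function(sites, cfg = filter_config()) {
  depth <- sites$meth + sites$unmeth
  keep <- depth >= cfg$min_depth
  if (isTRUE(cfg$require_both_strands) && nrow(sites)) {
    off <- integer(nrow(sites))
    off[sites$context == "CpG"] <- 1L
    off[sites$context == "CHG"] <- 2L
    off <- ifelse(sites$strand == "+", off, -off)
    partner_strand <- ifelse(sites$strand == "+", "-", "+")
    key <- paste(sites$chrom, sites$pos, sites$strand)
    pkey <- paste(sites$chrom, sites$pos + off, partner_strand)
    partner_ok <- keep[match(pkey, key)]
    partner_ok[is.na(partner_ok)] <- FALSE
    sym <- sites$context %in% c("CpG", "CHG")
    keep <- keep & (!sym | partner_ok)
  }
  sites[keep, , drop = FALSE]
}

# context calls from a character vector of one chromosome's plus-strand bases
.context_calls <- function(chars, pos, strand) {
  n <- length(chars)
  stopifnot(all(pos >= 1L & pos <= n))
  base <- chars[pos]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  onstrand <- ifelse(strand == "+", base, unname(comp[base]))
  bad <- is.na(onstrand) | (onstrand != "C" & onstrand != "N")
  if (any(bad))
    stop("base at position ", pos[which(bad)[1L]], " is not C on strand ",
         strand[which(bad)[1L]])
  # next two bases downstream on the site's strand
  p1 <- ifelse(strand == "+", pos + 1L, pos - 1L)
  p2 <- ifelse(strand == "+", pos + 2L, pos - 2L)
  get <- function(p) ifelse(p >= 1L & p <= n, chars[pmax(pmin(p, n), 1L)], NA_character_)
  b1 <- get(p1); b2 <- get(p2)
  b1 <- ifelse(strand == "+", b1, unname(comp[b1]))
  b2 <- ifelse(strand == "+", b2, unname(comp[b2]))
  ctx <- ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
  undet <- onstrand == "N" | is.na(b1) | is.na(b2) | b1 == "N" | b2 == "N"
  ctx[undet] <- NA_character_
  tri <- paste0(onstrand, b1, b2)
  tri[undet & (is.na(b1) | is.na(b2))] <- NA_character_
  list(context = ctx, tri = tri)
}

#' Classify the sequence context of cytosine positions
#'
#' Determines the methylation context of a cytosine from the reference: with
#' b1 and b2 the next two bases downstream on the site's own strand, b1 = G
#' gives CpG, otherwise b2 = G gives CHG, otherwise CHH. Any N or sequence
#' end inside the trinucleotide makes the context undeterminable (`NA`). The
#' referenced base must be C on the given strand (G on the plus strand for
#' minus-strand sites), otherwise an error is raised.
#'
#' @param genome A [Biostrings::DNAStringSet] reference.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param tri Also return the trinucleotide? If TRUE the result is a data
#'   frame with columns `context` and `tri`.
#' @return Character vector of `"CpG"`, `"CHG"`, `"CHH"` or `NA`
#'   (undeterminable), or a data frame when `tri = TRUE`.
#' @export
classify_context <- function(genome, chrom, pos, strand, tri = FALSE) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  ctx <- rep(NA_character_, length(pos))
  trin <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    if (!(ch %in% names(genome))) stop("chromosome '", ch, "' not in genome")
    idx <- which(chrom == ch)
    chars <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]]
    cc <- .context_calls(chars, pos[idx], strand[idx])
    ctx[idx] <- cc$context
    trin[idx] <- cc$tri
  }
  if (tri) data.frame(context = ctx, tri = trin, stringsAsFactors = FALSE) else ctx
}

#' Annotate cytosine sites with genomic region
#'
#' Assigns each position a single region label: inside any exon of any gene
#' -> exonic (attributed to that gene; the lowest `gene_id` wins if exons of
#' several genes overlap); else inside any gene span -> intronic; else
#' intergenic. Gene strand is ignored. Positions on chromosomes absent from
#' the annotation are intergenic, with a warning.
#'
#' @param sites Data frame with at least `chrom` and `pos` columns.
#' @param models A [gene_models()] object.
#' @return Data frame with columns `region` (`"exonic"`, `"intronic"`,
#'   `"intergenic"`) and `gene_id` (`NA` for intergenic) aligned with
#'   `sites`.
#' @export
annotate_region <- function(sites, models) {
  n <- nrow(sites)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L || !nrow(models$genes))
    return(data.frame(region = region, gene_id = gene_id,
                      stringsAsFactors = FALSE))
  absent <- setdiff(unique(sites$chrom), unique(models$genes$chrom))
  if (length(absent))
    warning("chromosome(s) absent from annotation, treated as intergenic: ",
            paste(absent, collapse = ", "))
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  pick_min_gene <- function(gr, ids) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
    if (!length(ov)) return(NULL)
    h <- data.frame(qi = S4Vectors::queryHits(ov),
                    g = ids[S4Vectors::subjectHits(ov)])
    h <- h[order(h$qi, h$g), , drop = FALSE]
    h[!duplicated(h$qi), , drop = FALSE]
  }
  if (nrow(models$exons)) {
    egr <- GenomicRanges::GRanges(models$exons$chrom,
                                  IRanges::IRanges(models$exons$start,
                                                   models$exons$end))
    hit <- pick_min_gene(egr, models$exons$gene_id)
    if (!is.null(hit)) {
      region[hit$qi] <- "exonic"
      gene_id[hit$qi] <- hit$g
    }
  }
  ggr <- GenomicRanges::GRanges(models$genes$chrom,
                                IRanges::IRanges(models$genes$start,
                                                 models$genes$end))
  hit <- pick_min_gene(ggr, models$genes$gene_id)
  if (!is.null(hit)) {
    left <- hit[region[hit$qi] == "intergenic", , drop = FALSE]
    region[left$qi] <- "intronic"
    gene_id[left$qi] <- left$g
  }
  data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Classify methylation intensity from a level percentage
#'
#' Levels at or below `hypo_max_pct` (default 30) are hypomethylated, at or
#' above `hyper_min_pct` (default 70) hypermethylated, and strictly between
#' the two, intermediate.
#'
#' @param level_pct Numeric vector of methylation levels in percent (0-100).
#' @param cfg A [filter_config()] carrying the thresholds.
#' @return Character vector of `"hypomethylated"`, `"intermediate"`,
#'   `"hypermethylated"`.
#' @export
classify_intensity <- function(level_pct, cfg = filter_config()) {
  if (any(!is.finite(level_pct) | level_pct < 0 | level_pct > 100))
    stop("level_pct must be in [0, 100]")
  ifelse(level_pct <= cfg$hypo_max_pct, "hypomethylated",
         ifelse(level_pct >= cfg$hyper_min_pct, "hypermethylated",
                "intermediate"))
}

#' Filter and fully classify cytosine sites
#'
#' Convenience wrapper running the whole per-site stage: depth filter,
#' methylation level, region annotation, intensity category, and (when a
#' reference genome is given) recomputation of the sequence context from the
#' reference. Sites whose context is undeterminable (Ns, contig ends) are
#' excluded with a message.
#'
#' @param sites Cytosine site data frame.
#' @param models A [gene_models()] object.
#' @param cfg A [filter_config()].
#' @param genome Optional [Biostrings::DNAStringSet]; when given, context
#'   and trinucleotide are recomputed from it (overriding the report).
#' @return Data frame of classified sites with added columns `level_pct`,
#'   `region`, `gene_id`, `intensity`.
#' @export
classify_sites <- function(sites, models, cfg = filter_config(),
                           genome = NULL) {
  out <- depth_filter(sites, cfg)
  if (!is.null(genome) && nrow(out)) {
    cc <- classify_context(genome, out$chrom, out$pos, out$strand, tri = TRUE)
    out$context <- cc$context
    out$tri <- cc$tri
  }
  undet <- is.na(out$context)
  if (any(undet)) {
    message(sum(undet), " site(s) with undeterminable context excluded")
    out <- out[!undet, , drop = FALSE]
  }
  depth <- out$meth + out$unmeth
  out$level_pct <- ifelse(depth > 0, 100 * out$meth / depth, NA_real_)
  ann <- annotate_region(out, models)
  out$region <- ann$region
  out$gene_id <- ann$gene_id
  out$intensity <- classify_intensity(out$level_pct, cfg)
  rownames(out) <- NULL
  out
}

#' Genome-wide methylation summary statistics
#'
#' Counts and percentage composition of methylated cytosine sites by
#' sequence context (CpG/CHG/CHH), intensity (hyper/hypo/intermediate) and
#' genomic region (intergenic/exonic/intronic), plus the plus/minus strand
#' split — the nine-row summary layout used for whole-methylome reporting.
#' A site counts as methylated iff its methylated-read count is at least
#' `cfg$min_meth_reads` (default 1). Percentages use methylated sites as the
#' denominator (so each triple sums to 100); shares of all depth-passing
#' sites are reported alongside.
#'
#' @param classified Output of [classify_sites()].
#' @param cfg A [filter_config()].
#' @return An object of class `meth_summary`: a list with `n_total`
#'   (depth-passing sites), `n_methylated`, `counts` (named list of count
#'   vectors by context/intensity/region/strand) and `pct` / `pct_passing`
#'   (matching percentage vectors; `NA` when the denominator is zero).
#' @export
summarize_methylation <- function(classified, cfg = filter_config()) {
  m <- classified$meth >= cfg$min_meth_reads
  meth <- classified[m, , drop = FALSE]
  tab <- function(x, lv) {
    out <- table(factor(x, levels = lv))
    stats::setNames(as.integer(out), lv)
  }
  counts <- list(
    context = tab(meth$context, .CONTEXTS),
    intensity = tab(meth$intensity,
                    c("hypermethylated", "hypomethylated", "intermediate")),
    region = tab(meth$region, c("intergenic", "exonic", "intronic")),
    strand = tab(meth$strand, c("+", "-")))
  nm <- nrow(meth)
  structure(list(
    n_total = nrow(classified),
    n_methylated = nm,
    counts = counts,
    pct = lapply(counts, function(x) pct(x, nm)),
    pct_passing = lapply(counts, function(x) pct(x, nrow(classified)))),
    class = "meth_summary")
}

#' @export
print.meth_summary <- function(x, digits = 2, ...) {
  cat("Methylation summary\n")
  cat("  sites passing depth filter:", x$n_total, "\n")
  cat(sprintf("  methylated sites: %d (%s%%)\n", x$n_methylated,
              format(round(pct(x$n_methylated, x$n_total), digits))))
  rows <- rbind(
    cbind(label = paste0("% ", names(x$counts$context)),
          count = x$counts$context, pctv = x$pct$context),
    cbind(label = paste0("% ", names(x$counts$intensity)),
          count = x$counts$intensity, pctv = x$pct$intensity),
    cbind(label = paste0("% ", names(x$counts$region)),
          count = x$counts$region, pctv = x$pct$region))
  for (i in seq_len(nrow(rows)))
    cat(sprintf("  %-20s %10s  %6s\n", rows[i, 1], rows[i, 2],
                format(round(as.numeric(rows[i, 3]), digits))))
  s <- x$counts$strand
  cat(sprintf("  strand split: + %d (%s%%) / - %d (%s%%)\n", s[1],
              format(round(x$pct$strand[1], digits)), s[2],
              format(round(x$pct$strand[2], digits))))
  invisible(x)
}

#' Flatten a methylation summary to a one-row-per-statistic table
#'
#' @param x A `meth_summary`.
#' @return Data frame with columns `statistic`, `count`, `pct_of_methylated`,
#'   `pct_of_passing`.
#' @export
summary_table <- function(x) {
  stopifnot(inherits(x, "meth_summary"))
  lab <- unlist(lapply(names(x$counts), function(g)
    paste0(g, ":", names(x$counts[[g]]))))
  data.frame(
    statistic = c("total_passing", "total_methylated", lab),
    count = c(x$n_total, x$n_methylated, unlist(x$counts, use.names = FALSE)),
    pct_of_methylated = c(NA, pct(x$n_methylated, x$n_total),
                          unlist(x$pct, use.names = FALSE)),
    pct_of_passing = c(NA, NA, unlist(x$pct_passing, use.names = FALSE)),
    stringsAsFactors = FALSE)
}
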