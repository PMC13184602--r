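#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-separated
#'   token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a reference genome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

.CONTEXTS <- c("CpG", "CHG", "CHH")

.normalize_context <- function(x, where = "context") {
  up <- toupper(x)
  out <- rep(NA_character_, length(x))
  out[up %in% c("CG", "CPG")] <- "CpG"
  out[up == "CHG"] <- "CHG"
  out[up == "CHH"] <- "CHH"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("unknown ", where, " token '", x[bad], "' at line ", bad)
  }
  out
}

#' Read a per-cytosine methylation report
#'
#' Parses the tab-separated per-cytosine report dialect emitted by bisulfite
#' aligners (Bismark CX reports): chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count, context, trinucleotide.
#' Context tokens are accepted case-insensitively and `CG` is mapped to
#' `CpG`. Rows with zero depth are retained (depth filtering happens later,
#' see [depth_filter()]). Gzip-compressed files are read transparently.
#'
#' @param path Path to a (optionally gzipped) cytosine report without header.
#' @return A data frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, `context`, `tri`.
#' @export
read_cytosine_report <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "pos", "strand", "meth",
                                    "unmeth", "context", "tri"),
                      colClasses = c("character", "integer", "character",
                                     "integer", "integer", "character",
                                     "character")),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(df$meth < 0 | df$unmeth < 0 | is.na(df$meth) | is.na(df$unmeth))
  if (length(bad))
    stop("parse error in '", path, "': negative or missing read count at line ",
         bad[1L], call. = FALSE)
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    stop("parse error in '", path, "': invalid strand '", df$strand[bad[1L]],
         "' at line ", bad[1L], call. = FALSE)
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad))
    stop("parse error in '", path, "': invalid position at line ", bad[1L],
         call. = FALSE)
  df$context <- .normalize_context(df$context)
  df
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: headerless 7-column TSV.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, `context`, `tri`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  need <- c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")
  stopifnot(all(need %in% names(sites)))
  utils::write.table(sites[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a validated set of gene models
#'
#' A gene model is a gene span plus its ordered, non-overlapping exon
#' intervals; introns are the gaps between consecutive exons. Coordinates are
#' 1-based inclusive, matching GFF3.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return An object of class `gene_models` (a list with elements `genes`
#'   and `exons`, exons sorted by gene and start).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in gene set")
  if (nrow(exons)) {
    miss <- setdiff(exons$gene_id, genes$gene_id)
    if (length(miss))
      stop("exon Parent does not resolve to a gene: ", miss[1L])
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    gs <- genes$start[match(exons$gene_id, genes$gene_id)]
    ge <- genes$end[match(exons$gene_id, genes$gene_id)]
    out <- exons$start < gs | exons$end > ge
    if (any(out))
      stop("exon outside its gene span for gene ", exons$gene_id[which(out)[1L]])
    sp <- split(seq_len(nrow(exons)), exons$gene_id)
    for (idx in sp) {
      if (length(idx) > 1L &&
          any(exons$start[idx][-1L] <= exons$end[idx][-length(idx)]))
        stop("overlapping exons within gene ", exons$gene_id[idx[1L]])
    }
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Intron intervals of gene models
#'
#' Introns are the gaps between consecutive exons of a gene; single-exon
#' genes have none.
#'
#' @param models A `gene_models` object.
#' @param gene_id Optional character vector restricting to specific genes.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (possibly zero rows).
#' @export
gene_introns <- function(models, gene_id = NULL) {
  ex <- models$exons
  if (!is.null(gene_id)) ex <- ex[ex$gene_id %in% gene_id, , drop = FALSE]
  if (!nrow(ex))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  sp <- split(ex, ex$gene_id)
  out <- lapply(sp, function(e) {
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features, resolves exon `Parent` attributes and
#' validates the result (exons within the gene span, non-overlapping within
#' a gene).
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gt <- gr[!is.na(gr$type) & gr$type == "gene"]
  et <- gr[!is.na(gr$type) & gr$type == "exon"]
  genes <- data.frame(
    gene_id = as.character(gt$ID),
    chrom = as.character(GenomicRanges::seqnames(gt)),
    strand = as.character(GenomicRanges::strand(gt)),
    start = GenomicRanges::start(gt),
    end = GenomicRanges::end(gt),
    stringsAsFactors = FALSE)
  genes$strand[!(genes$strand %in% c("+", "-"))] <- "+"
  parent <- if (length(et)) vapply(as.list(et$Parent), function(p) {
    if (!length(p)) NA_character_ else as.character(p[[1L]])
  }, character(1)) else character(0)
  if (anyNA(parent)) stop("exon without Parent attribute in '", path, "'")
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(et)),
    start = GenomicRanges::start(et),
    end = GenomicRanges::end(et),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons
  if (!nrow(g)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                strand = g$strand)
  ggr$type <- "gene"
  ggr$ID <- g$gene_id
  if (nrow(e)) {
    estr <- g$strand[match(e$gene_id, g$gene_id)]
    egr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                  strand = estr)
    egr$type <- "exon"
    egr$ID <- NA_character_
    egr$Parent <- e$gene_id
    ggr$Parent <- NA_character_
    gr <- c(ggr, egr)
  } else {
    gr <- ggr
  }
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), gr$type)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a tab-separated table with header
#'
#' All tabular pipeline outputs (gene-level records, contrast summaries,
#' chromosome counts) go through this writer: TSV with header, stable column
#' order, numeric columns rounded to a fixed precision, and a validation
#' error if any character field contains a tab or newline (which would break
#' the format).
#'
#' @param records Data frame.
#' @param path Output path.
#' @param digits Number of decimal places kept for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = 6L) {
  stopifnot(is.data.frame(records))
  for (nm in names(records)) {
    col <- records[[nm]]
    if (is.character(col) || is.factor(col)) {
      if (any(grepl("[\t\n]", as.character(col))))
        stop("field '", nm, "' contains a tab or newline; refusing to write TSV")
    } else if (is.double(col)) {
      records[[nm]] <- round(col, digits)
    }
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#'
#' @param path Path to a TSV file with header.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' A sample sheet maps samples to the study factors: TSV with header and
#' columns `sample_id`, `genotype`, `condition`, `stage`, `report_path`.
#' Sample ids must be unique; report paths are resolved relative to the
#' sheet's directory and must exist.
#'
#' @param path Path to the sample sheet.
#' @param check_paths Verify that every `report_path` exists (default TRUE).
#' @return Data frame of the sheet with `report_path` resolved.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  sheet <- read_table(path)
  need <- c("sample_id", "genotype", "condition", "stage", "report_path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  resolved <- ifelse(file.exists(sheet$report_path), sheet$report_path,
                     file.path(dirname(path), sheet$report_path))
  if (check_paths && !all(file.exists(resolved)))
    stop("report path(s) not found: ",
         paste(sheet$report_path[!file.exists(resolved)], collapse = ", "))
  sheet$report_path <- resolved
  sheet
}
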