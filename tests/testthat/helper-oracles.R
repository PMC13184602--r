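# Shared fixtures and independent brute-force oracles used across tests.

# A tiny hand-made gene model set: gene 100-200 with exons 100-150 and
# 181-200, single-exon gene 300-400, on chr1.
tiny_models <- function() {
  gene_models(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       strand = c("+", "-"), start = c(100L, 300L),
                       end = c(200L, 400L), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                       start = c(100L, 181L, 300L), end = c(150L, 200L, 400L),
                       stringsAsFactors = FALSE))
}

make_sites <- function(pos, meth, unmeth, chrom = "chr1", strand = "+",
                       context = "CpG", tri = "CGA") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             context = context, tri = tri, stringsAsFactors = FALSE)
}

# Independent context oracle: string operations on the forward sequence and
# its literal reverse complement, no shared code with classify_context().
oracle_context_plus <- function(seq_string, pos) {
  tri <- substring(seq_string, pos, pos + 2L)
  vapply(tri, function(t) {
    if (nchar(t) < 3L || grepl("N", t)) return(NA_character_)
    if (substr(t, 2L, 2L) == "G") "CpG"
    else if (substr(t, 3L, 3L) == "G") "CHG"
    else "CHH"
  }, character(1), USE.NAMES = FALSE)
}

oracle_context <- function(seq_string, pos, strand) {
  L <- nchar(seq_string)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq_string), "",
                           fixed = TRUE)[[1L]]), collapse = "")
  out <- character(length(pos))
  plus <- strand == "+"
  out[plus] <- oracle_context_plus(seq_string, pos[plus])
  out[!plus] <- oracle_context_plus(rc, L - pos[!plus] + 1L)
  out
}

# Independent region oracle: per-base label array filled by direct scans of
# the gene model table (exon overwrites intron overwrites intergenic; among
# overlaps the lowest gene_id wins because it is written last).
oracle_region <- function(models, chrom, chrom_len) {
  lab <- rep("intergenic", chrom_len)
  gid <- rep(NA_character_, chrom_len)
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  e <- models$exons[models$exons$chrom == chrom, , drop = FALSE]
  for (i in order(g$gene_id, decreasing = TRUE)) {
    lab[g$start[i]:g$end[i]] <- "intronic"
    gid[g$start[i]:g$end[i]] <- g$gene_id[i]
  }
  exon_gid <- rep(NA_character_, chrom_len)
  for (i in order(e$gene_id, decreasing = TRUE)) {
    lab[e$start[i]:e$end[i]] <- "exonic"
    exon_gid[e$start[i]:e$end[i]] <- e$gene_id[i]
  }
  gid[lab == "exonic"] <- exon_gid[lab == "exonic"]
  gid[lab == "intergenic"] <- NA_character_
  list(region = lab, gene_id = gid)
}

# Step-up BH adjustment written out from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in seq(m, 1L)) {
    q[i] <- if (i == m) ranked[i] else min(ranked[i], q[i + 1L])
  }
  pmin(1, q)[order(o)]
}

# Exact two-sided signed-rank p for distinct nonzero deltas by full
# enumeration of all sign assignments.
oracle_signed_rank_p <- function(deltas) {
  r <- rank(abs(deltas))
  n <- length(deltas)
  v_obs <- sum(r[deltas > 0])
  signs <- expand.grid(rep(list(c(0L, 1L)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

sim_small <- function(seed = 1L, ...) {
  sim_config(genome_length = 30000L, n_chromosomes = 2L, n_genes = 10L,
             gene_length = c(600L, 1000L), seed = seed, ...)
}
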