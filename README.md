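# gbmeth — gene-body methylation analysis for WGBS

`gbmeth` is an R package for the post-alignment stage of whole-genome
bisulfite sequencing (WGBS) studies: it takes per-cytosine methylation
reports (the Bismark CX dialect), a reference FASTA and GFF3 gene models,
and carries the analysis through site classification, gene-level exonic
aggregation, condition contrasts and multivariate pattern discovery. It was
built for studies of methylation stability in clonally propagated crops —
comparing tissue-culture stages against a mother plant, or drought
treatments against a watered control — but nothing in it is specific to
that design.

It is aimed at plant epigenomics practitioners who have already run
trimming, alignment and methylation extraction with the standard tools and
want a tested, reproducible implementation of everything after that.

## What it computes

For each sample, every cytosine site with read depth ≥ 5 is classified by

* **sequence context** — CpG, CHG, CHH from the two downstream bases on the
  site's own strand;
* **genomic region** — exonic, intronic or intergenic by containment in the
  gene models (exon > intron > intergenic precedence);
* **intensity** — from its level `100·m/(m+u)`: hypomethylated (≤ 30%),
  intermediate, hypermethylated (≥ 70%).

Gene-body methylation is the read-weighted level over a gene's exonic
sites, `L_g = 100 · Σ m_i / Σ (m_i + u_i)`. For a test condition *t* versus
reference *r*, per-gene deltas `Δ_g = L_g(t) − L_g(r)` are formed over the
genes methylated in at least one condition; the package reports

* the genome-wide shift `median(Δ)` and across-loci variability `sd(Δ)`;
* a two-sided paired Wilcoxon signed-rank p-value with Benjamini–Hochberg
  q-values across the stage family;
* differentially methylated genes (|Δ| ≥ 10 points by default);
* the percent change in methylated-gene counts, `100·(n_t − n_r)/n_r`;
* one-way ANOVA + Fisher's LSD letter groups on chromosome-wise counts of
  hypermethylated exonic positions (condition × context groups);
* PCA of the top-500 most variable features, hierarchical clustering of
  genes hypermethylated in every sample, and Venn overlap counts.

A first-class synthetic-data module (`sim_config()`, `simulate_genome()`,
`simulate_methylome()`, `simulate_study()`) generates genomes, gene models
and cytosine reports with known ground truth, so the entire pipeline is
testable at desk scale.

## Worked example

```r
library(gbmeth)

cfg <- sim_config(effect_size = 4, affected_fraction = 1,
                  depth_mean = 20, seed = 7)
g <- simulate_genome(cfg)
recs <- lapply(c("control", "treated"), function(cond) {
  sim <- simulate_methylome(cfg, g$genome, g$models, cond)
  cls <- classify_sites(sim$report, g$models, genome = g$genome)
  aggregate_genes(cls, g$models, cond)
})
contrast_genes(recs[[2]], recs[[1]], contrast_spec("treated", "control"))
```

```
Contrast: treated vs control (reference)
  genes in universe: 25
  median shift: +3.17 points (sd across loci 2.23)
  Wilcoxon signed-rank p = 1.192e-07, BH q = 1.192e-07
  DMGs (|delta| >= 10): 0
  methylated genes: 25 (test) vs 25 (ref), change +0.00%
```

The simulation imposed a +4-point methylation shift on the exonic sites of
every gene; the median of the per-gene deltas recovers it up to binomial
read-sampling noise and depth-filter attrition (+3.17 points here, at the
default mean depth; recovery tightens to ±0.5 points at 500 genes, see the
methods vignette), and the signed-rank test finds the shift overwhelmingly
significant. No single gene moves by ≥ 10 points, so no DMGs are called —
a genome-wide drift rather than gene-specific remodeling. Per-sample
summaries print the nine-row composition table (context / intensity /
region shares of methylated sites, each triple summing to 100%) plus the
plus/minus strand split:

```r
sim <- simulate_methylome(cfg, g$genome, g$models, "control")
summarize_methylation(classify_sites(sim$report, g$models, genome = g$genome))
```

A thin command-line wrapper with `simulate`, `classify`, `aggregate`,
`contrast`, `patterns` and `run` subcommands is installed at
`system.file("scripts/pipeline.R", package = "gbmeth")`; the `run`
subcommand executes the whole pipeline from a sample sheet and writes a
manifest with per-file checksums for reproducibility.

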