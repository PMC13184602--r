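---
title: "Methods: gene-body methylation analysis with gbmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-body methylation analysis with gbmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmeth)
```

# Scope and model

`gbmeth` analyses whole-genome bisulfite sequencing (WGBS) data from the
point where an aligner's methylation extractor has produced per-cytosine
reports: tab-separated rows of chromosome, 1-based position, strand,
methylated read count, unmethylated read count, sequence context and
trinucleotide (the Bismark CX dialect). Everything upstream — trimming,
alignment, deduplication — is out of scope and assumed done by the standard
tools.

The analysis pipeline is:

1. **Site filtering and classification.** Sites must reach a minimum read
   depth (default 5, boundary inclusive). Each surviving site is labelled
   three ways: *sequence context* (CpG, CHG, CHH — from the two bases
   downstream of the cytosine on its own strand), *genomic region* (exonic,
   intronic, intergenic — by containment in gene-model intervals), and
   *methylation intensity* from its level `100 * meth / (meth + unmeth)`:
   hypomethylated (≤ 30%), intermediate (strictly between), hypermethylated
   (≥ 70%).
2. **Gene-level aggregation.** Exonic sites are aggregated per gene into a
   read-weighted methylation level, `100 * Σ meth / Σ (meth + unmeth)`. The
   exon-only focus keeps the quantity directly interpretable in terms of
   gene-body methylation, which in plants marks stably expressed genes.
3. **Contrast statistics.** For a test condition against its reference
   (e.g. drought vs control, or a subculture stage vs the mother plant),
   per-gene deltas are formed over the genes methylated in at least one of
   the two conditions and covered in both. The genome-wide effect size is
   the **median** of these deltas; across-loci variability is their n−1
   standard deviation. Significance uses the two-sided **paired Wilcoxon
   signed-rank test** on the deltas, with **Benjamini–Hochberg** adjustment
   across the stages of a contrast family. Genes with |delta| beyond a
   threshold (default 10 points) are called differentially methylated
   (DMGs). Chromosome-wise counts of hypermethylated exonic positions are
   compared across condition × context groups by one-way ANOVA followed by
   **Fisher's LSD** at α = 0.05, summarised as a compact letter display.
4. **Pattern discovery.** PCA of samples on the top-k most variable
   features, hierarchical clustering of genes hypermethylated in every
   sample, and inclusion–exclusion (Venn) overlap counts of methylated gene
   sets.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth` | 5 | reads | high-confidence sites; boundary inclusive (depth 5 passes) |
| `hypo_max_pct` / `hyper_min_pct` | 30 / 70 | % | fixed intensity bins; both boundaries inclusive for their bin |
| `min_meth_reads` | 1 | reads | a site "is methylated" iff ≥ 1 methylated read at a depth-passing site |
| `dmg_delta_threshold` | 10 | points | DMG call on the gene-level delta |
| `alpha` | 0.05 | — | Wilcoxon/BH and ANOVA/LSD significance |
| `top_k` | 500 | features | most-variable features entering the PCA |

Decisions taken where the procedure was genuinely open:

* **"Methylated site" definition.** Whole-methylome summaries need a
  methylated/unmethylated dichotomy. We use ≥ 1 methylated read at a
  depth-passing site. Any level-based definition high enough to be
  stringent would empty the hypomethylated (≤ 30%) bin, which must be
  populable; the minimum methylated-read count is configurable.
* **Depth "on both strands".** CHH sites have no strand-symmetric partner,
  so a universal both-strand depth rule is impossible. Default is per-site
  depth; `require_both_strands = TRUE` additionally requires the symmetric
  partner position of CpG (±1 bp) and CHG (±2 bp) sites to pass.
* **Region precedence.** A position inside an exon of any gene is exonic
  even if it is intronic in an overlapping gene (exon > intron >
  intergenic); attribution goes to the lowest gene identifier for
  determinism. Gene strand is ignored: methylation on either strand within
  an exon interval is exonic.
* **Weighted vs unweighted gene level.** The read-weighted level is robust
  to depth heterogeneity among a gene's sites; the unweighted mean of site
  levels is available (`weighted = FALSE`) for sensitivity analysis. Sites
  shared by exons of two overlapping genes count in both gene records, so
  each record is self-contained.
* **Wilcoxon details.** Zero deltas are dropped before ranking (Wilcoxon's
  original treatment rather than Pratt's); the exact null distribution is
  used for ≤ 25 nonzero deltas without ties, the normal approximation with
  continuity correction and midrank tie handling otherwise. All-zero delta
  vectors are degenerate: p is reported as 1 with a flag.
* **BH family.** All stages within one contrast set (e.g. the five
  subculture stages of one culture type against the mother plant) form one
  adjustment family.
* **DMG normalisation.** The DMG count is also reported per 100 points of
  the observed absolute-delta range, one defensible reading of
  "per 100-point methylation difference"; it is labelled as such and never
  substituted for the raw count.
* **Degenerate ANOVA.** Exactly constant groups leave floating-point dust
  in the mean squares; both mean squares are snapped to zero below a
  scale-aware tolerance. Zero residual variance with distinct means yields
  F = ∞, p = 0, and LSD separates any two unequal means; zero variance
  everywhere yields a single shared letter.
* **Compact letters.** Letters are assigned per maximal all-pairwise-
  not-significant subset (exact enumeration; the design produces ≤ 9
  groups), so groups sharing a letter never differ at α and groups that do
  not differ always share one.
* **PCA.** Centred, unscaled levels (all features share percentage units);
  scaling is a flag. Features are restricted to complete cases across
  samples before variance ranking — no imputation. Variable-selection ties
  are broken by feature identifier.
* **Clustering.** Euclidean distance, average linkage by default;
  dendrograms are exported as Newick. The sample axis is clustered by
  default.
* **Percent change.** Reported signed with two decimals; the package never
  silently rounds. Note the algebraic reversal identity is
  `pc(a,b) = -pc(b,a) * b / a`.

# The synthetic-data generator

Real WGBS studies at genome scale cannot be reproduced at desk scale, so
the generator emulates the *statistical structure* of the inputs with known
ground truth:

* **Genome and gene models.** Random A/C/G/T sequence at GC ≈ 0.42 over
  `chr1..chrN`; non-overlapping genes with exon/intron structure and
  intergenic space. Defaults (200 kb, 25 genes of 0.8–1.6 kb, exons ≈ 40%
  of the gene span) put roughly 84% of the genome intergenic, 6% exonic and
  10% intronic, matching the region proportions typical of a plant genome.
  An `n_rate` option injects Ns to exercise undeterminable-context
  handling.
* **Methylation probabilities.** Each site draws a baseline probability
  from a beta distribution around its context's mean — defaults CpG 0.80,
  CHG 0.50, CHH 0.10, the canonical high/intermediate/low plant gene-body
  pattern — with concentration `rate_dispersion` (default 5, giving
  realistic site-to-site spread). Baselines are drawn once per study from
  the configuration seed, so every condition shares them: a treatment
  effect of *e* points shifts exonic sites of affected genes by exactly
  `e/100` (clamped to [0, 1]) before any sampling noise, which is what
  makes parameter-recovery tests exact at the truth-table level and the
  design genuinely paired.
* **Reads.** Depth is negative-binomial (mean `depth_mean`, size
  `depth_dispersion`), deliberately overdispersed so sites fall on both
  sides of the depth-5 filter; methylated counts are binomial. Each
  condition and replicate has its own deterministic sampling stream derived
  from the seed, so identical configurations are byte-reproducible and
  zero-effect conditions are exchangeable.
* **Pooling.** One report per condition by default, mirroring a design
  that pools biological replicates before sequencing;
  `n_samples_per_condition > 1` emits replicated reports.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: bisulfite conversion errors and M-bias, PCR
duplicates, mappability gaps, transposable-element structure, correlated
methylation along the genome (sites are independent given their context),
and genotype-specific sequence differences. Conclusions from the simulated
studies concern the correctness and calibration of the *computations*, not
biological effect sizes.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in all external formats (reports,
  GFF3); interval work inside the package is delegated to
  IRanges/GenomicRanges, converting only at the I/O boundary.
* Context tokens are accepted case-insensitively; `CG` maps to `CpG`.
* Zero-depth rows are retained by the reader and removed by the depth
  filter; undeterminable contexts (N in the trinucleotide, contig ends)
  are excluded from all statistics with a message.
* Zero methylated sites: counts are reported as zeros and percentage
  shares as `NA`, never 0/0.
* Median for an even number of deltas is the mean of the central pair; all
  standard deviations use the n−1 denominator.
* Empty gene universe (no gene methylated in either condition) is a
  contrast error; a pipeline run logs it and continues with the remaining
  contrasts.

# Problem sizes used by the test and acceptance suites

The package's own verification runs at desk scale, chosen to keep the full
suite in single-digit minutes while leaving the statistical checks
well-powered: classification oracles on ≤ 100 kb genomes (~40,000 cytosine
sites) against independent per-base scans; median-shift recovery of
imposed +1/+2/+4-point effects on 500 genes at mean depth 20 (each shift
recovered within ±0.5 points); and the type-I error of the paired Wilcoxon
test estimated from 1,000 null contrasts on a 30-gene genome, required to
fall inside the binomial 99% interval around the nominal 0.05.

# A worked example

```{r example, eval = FALSE}
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

# Known limitations

* Site-level differential methylation (DMR calling) is not implemented;
  the unit of inference is the gene (exonic aggregate).
* Promoter, flank and transposable-element aggregation are out of scope.
* The contrast layer compares one sample per condition (pooled designs);
  replicate-aware models (e.g. beta-binomial regression) are not provided.
* BAM/SAM parsing and bedGraph output are not supported; input starts at
  the per-cytosine report.
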