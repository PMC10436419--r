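---
title: "Methods and design of the lncmast pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lncmast pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmast)
```

`lncmast` is an end-to-end analysis pipeline for long noncoding RNA
(lncRNA) studies in bovine subclinical mastitis with dietary intervention
designs. The canonical design has four groups — subclinical-mastitis
folic-acid-fed (SF) and control (SC), healthy fed (HF) and control (HC) —
with somatic cell count (SCC, ×1000 cells/mL) as the udder-health
phenotype, and the analysis proceeds from assembled transcripts to a
lncRNA catalog, differential expression, co-expression modules, target
prediction, and genetic-evidence integration (QTL intervals and GWAS
summary statistics). This vignette documents the models, parameter
defaults, numerical choices and known limitations of each stage, and what
the synthetic-data validation does and does not demonstrate.

## Identification of putative lncRNAs

The catalog is built from a gffcompare-style assembly GTF by a filter
cascade:

1. **Basic filter.** Keep transcripts with `exon_count >= 2`,
   `length >= 200` nt, and maximum per-sample read count `>= 1`.
   Transcripts whose class code is `=` and whose matched reference
   transcript is annotated with biotype `lncRNA` bypass the exon filter:
   single-exon *known* lncRNAs are legitimate, while single-exon novel
   fragments are common assembly artifacts. The read-count rule is
   interpreted as "maximum over samples ≥ 1"; a per-sample or total-count
   interpretation is possible and the threshold is exposed as `min_count`.
2. **Class-code filter.** Novel candidates are the class codes `i`
   (intronic), `u` (intergenic) and `x` (exonic antisense); `=` matches
   are routed to the known-lncRNA check; everything else is discarded with
   per-code counts. We read class codes from the standard `class_code`
   attribute and the matched reference transcript from `cmp_ref`.
3. **Coding-potential consensus.** A transcript is called noncoding only
   when *all* enabled predictors agree — the same strict-intersection
   logic used when combining multiple coding-potential tools. The
   built-in predictors are:
   - **ORF length**: longest forward-frame ATG→stop ORF (stop included),
     ties to the 5′-most start; noncoding iff `< 300` nt. Transcripts are
     assumed already oriented, so the reverse strand is not scanned.
   - **Fickett TESTCODE**: the classical position/composition statistic
     with the published 10-bin lookup tables; noncoding iff `< 0.95`.
   - **Hexamer usage**: mean log2 ratio of coding to noncoding hexamer
     frequencies over the in-frame hexamers of the longest ORF (0 when
     there is no ORF); noncoding iff `< 0`. Default tables derive the
     coding side from a mammalian codon-usage table (adjacent-codon
     products, stops excluded) and the noncoding side from a mildly
     AT-rich i.i.d. model (A = T = 0.3, C = G = 0.2); study-specific
     tables can be trained with `train_hexamer()`.
   - **Composite**: `plogis(1.5 (orf/300 − 1) + 3 (fickett − 0.95) +
     2 hexamer)`, noncoding iff `< 0.5`. The weights place the decision
     boundary at the three marginal thresholds and are deliberately
     simple and documented rather than fitted.
   External per-tool score tables can be supplied and enter the same
   intersection (negative score = noncoding); transcripts missing from an
   external table are conservatively treated as coding.
4. **Classification.** `u` → lincRNA, `i` → ilncRNA, `x` → lncNAT,
   reference-matched → known. Known lncRNAs are accepted on the strength
   of their reference annotation and do not pass through the
   coding-potential screen, mirroring the usual treatment of
   database-annotated lncRNAs.

## Differential expression

Counts are normalized by **median-of-ratios** size factors (computed over
features with all-positive counts, geometric-mean rescaled; total-count
fallback with a warning when no such feature exists). Downstream
correlation analyses use `log2(count/size_factor + 1)`. This transform
replaces regularized-log shrinkage: it is monotone, dependency-free and
easy to reason about, and every correlation threshold used downstream is
re-validated on synthetic data generated under this transform rather than
assumed transferable from other pipelines.

The per-feature test models counts as negative binomial. Group means are
estimated on normalized counts; the NB dispersion is estimated by the
method of moments pooled within groups and shrunk 50/50 toward the
across-feature trend (the mean of the raw moment estimates — the raw,
possibly negative estimates enter the trend so that sampling noise
cancels rather than accumulating through a floor; the final dispersion is
floored at zero). The Wald statistic is the log2 fold change (treatment
over control, 0.5 pseudocount) over its delta-method standard error, with
two-sided p-values from the standard normal: the dispersion blending
keeps the statistic close to normal even at n = 3–4 per group, and the
null rejection rate at 0.05 is verified by simulation (2,000 null
features, near-Poisson, large counts) to lie within the exact binomial
99% interval.

**Calling rule.** A feature is `up` iff `log2FC > 1` and `p < 0.05`
(`down` symmetric), with both inequalities strict. Calling uses the *raw*
p-value: the worked DE tables this pipeline reproduces print raw
p-values, and applying the rule to them must reproduce their published
shared-DE counts. BH-adjusted p-values are always reported alongside and
can be used for calling by passing them as the `pvalue` column. This
choice is deliberate and prominent: with raw p < 0.05 the empirical FDR
is controlled only loosely (see the recovery results below).

## Co-expression modules

The module analysis follows the weighted-network recipe on the
protein-coding genes (at most `max_module_genes = 500` most-variable
genes in the pipeline driver, which keeps the O(genes²) TOM affordable):

- **Unsigned adjacency** `|cor|^β`. The soft threshold β is the smallest
  power (1–20) whose scale-free topology fit R² exceeds 0.9, where the
  fit regresses log10 frequency on log10 connectivity over 10 bins; if no
  power reaches the target the best one is used with a warning.
- **Topological overlap** `TOM_ij = (L_ij + a_ij)/(min(k_i,k_j) + 1 −
  a_ij)`, average-linkage clustering on `1 − TOM`.
- **Cut selection.** Instead of the reference dynamic tree cut, the tree
  is cut at the height (scanned over the merge-height quantiles) that
  maximizes weighted modularity of the induced partition on the adjacency
  graph, with sub-`min_module_size` (default 30) clusters going to grey.
  Two refinement passes follow: candidate modules whose eigengene
  explains less than `min_pc1_share = 0.3` of member variance are
  dissolved, then members with `|kME| < 0.5` are pruned and grey genes
  with `|kME| ≥ 0.7` are rescued (kME = correlation with the module
  eigengene). The pruning/rescue pass is what keeps loose aggregations of
  background genes from surviving as modules at small sample sizes.
- **Eigengenes and traits.** The module eigengene is the first principal
  component of standardized member expression, sign-oriented so the mean
  member correlation is positive. Module–trait association is the Pearson
  correlation of the eigengene with each trait column (group indicators
  and SCC), with t-distribution p-values on n − 2 degrees of freedom and
  a P < 0.05 significance flag. Module selection beyond that flag is left
  to the analyst: the result is a ranked table, not an automatic cut.

## Target prediction

- **Cis targets**: protein-coding genes whose span lies within 100 kb of
  the lncRNA span on the same chromosome, strand ignored. The gap is
  `max(0, max(starts) − min(ends))` — zero for overlapping intervals and
  a simple end-to-start difference otherwise, which reproduces printed
  QTL-table distances exactly. Windows anchor on the transcript span (not
  the TSS). Pairs within 1 kb are flagged as proximal.
- **Trans targets**: Pearson correlation of normalized log expression
  between DE lncRNAs and DE mRNAs, computed within each comparison's
  samples only (SF+SC: n = 8; HF+HC: n = 6) — cross-cohort correlation
  conflates group structure with co-regulation and is disabled by
  default. A pair is kept iff `|R| > 0.95` and the two-sided t-transform
  p < 0.05. Note that at n = 8 the `|R| > 0.95` rule is far stricter than
  p < 0.05 alone; under the null its retention rate equals the analytic
  t-tail, which the tests verify.
- **Binding screen**: a deliberately simplified duplex-energy model. The
  lncRNA is slid along the reverse complement of the target; at each
  offset the best contiguous complementary stretch is scored with a
  nearest-neighbor RNA stacking table (no loops, bulges or dangling
  ends), and the minimum over offsets is normalized by the shorter
  sequence length. The binding call uses `ndG < −0.08` (strict) for
  interface parity with full thermodynamic screens, but the energies are
  *not* thermodynamically accurate and the screen should be read as a
  coarse complementarity filter.
- **SCC regression**: per-gene OLS of normalized expression on SCC with
  the two-sided slope p-value.

## QTL overlap and GWAS enrichment

DE lncRNAs are screened against QTL intervals with the same ±100 kb gap
rule (point-like QTL records are ordinary intervals; no minimum width).
GWAS integration uses a **sum-based enrichment statistic**: per-SNP
signal is the χ²₁ quantile at 1 − p, the observed statistic sums the
signal over SNPs within 50 kb of any member gene (closed intervals), and
the null redraws `n_perm` random gene sets of the same size from the gene
universe — randomizing genes rather than SNP positions preserves the
SNP-signal spatial structure. The empirical p-value is
`(1 + #{null ≥ observed})/(1 + n_perm)`, reproducible bit-for-bit under a
fixed seed. For display the conventional enrichment degree
`|log10(p + 1)|` is emitted (a bounded transform, at most `log10 2`);
because it is unusual, the plain `−log10 p` is always emitted alongside.
"Significant SNP" counting in the per-gene report defaults to the
genome-wide 5e−8 threshold, configurable.

## Over-representation analysis

Gene lists are tested against user-supplied GMT sets with the one-sided
hypergeometric upper tail, BH-corrected across terms. The universe
defaults to the expressed genes (those passing the count prefilter), not
the whole annotation — the standard guard against expression-bias
inflation. Default significance flags: adjusted p < 0.01 for GO-style
collections, < 0.05 for pathway-style collections.

## The synthetic data generator

All validation runs on data from `simulate_dataset()`, a pure function of
(configuration, seed) whose ground truth is sufficient to score every
stage. The default study conditions are fixed once:

- **Design**: 14 samples (SF 4, SC 4, HF 3, HC 3); SCC log-normal with
  median 600 (S groups) vs. 100 (H groups) ×1000 cells/mL, sdlog 0.4 —
  consistent with the > 500 ×1000 cells/mL classification rule for
  subclinical mastitis.
- **Genome**: 3 chromosomes × 5 Mb carrying 300 coding genes and 120
  noncoding transcripts (40 intergenic, 25 intronic, 35 antisense, 20
  known), sized so the full pipeline runs in seconds. Class-u transcripts
  are placed beyond the 100 kb window from any gene; class-i strictly
  inside host introns; class-x across a host exon on the opposite strand.
  15% of noncoding transcripts violate exactly one identification filter
  (single exon, length < 200, zero counts, or coding-like sequence) so
  the filters have work to do; violators are excluded from the true
  catalog.
- **Sequences**: coding transcripts carry an embedded ORF (≥ 300 nt where
  length permits) with mammalian codon usage; noncoding sequences are
  drawn from the AT-rich composition and post-processed so no ORF reaches
  150 nt.
- **Counts**: NB with log-normal baseline means (median 300, sdlog 1) and
  log-normal dispersions around 0.1 (typical bulk RNA-seq scale); library
  size factors span ≥ 2-fold. Planted DE features (40 mRNAs + 12 lncRNAs
  per comparison, 10 mRNAs shared between comparisons) get effects of
  |log2FC| ∈ [2, 3.5] on baselines ≥ 100 — the generator plants effects
  on adequately expressed features because power at very low counts is
  not what the recovery floors are meant to probe. Three modules of 50
  coding genes share latent factors; the first is strongly tied to the
  S/H contrast (its eigengene–group correlation is the planted
  module–trait signal) while later modules are mostly independent so that
  modules remain mutually separable. Ten genes are linear in standardized
  log SCC (±0.8 per SD).
- **QTL/GWAS**: eight planted QTLs within the ±100 kb window of chosen DE
  lncRNAs (4 bp intervals, like database point records), decoys in a
  reserved chromosome tail > 100 kb from every transcript; GWAS SNP
  panels per trait with uniform p-values except a non-central χ² signal
  (ncp 12) within 50 kb of 15 planted genes on the "Somatic cell score"
  trait.

**Scoring conventions.** Two scoring exclusions are deliberate. The
module-recovery ARI excludes planted DE genes: their shared group-mean
shifts make them genuinely co-expressed, so they are neither background
nor members of a planted module. The DE empirical FDR excludes planted
module/SCC genes from the false-positive count: their sample-level latent
variation produces real per-realization mean differences, so they are not
null features (a test assuming within-group independence is expectedly
anticonservative for them, as it would be for correlated real data).

**What passing does and does not show.** The generator emulates the
statistical structure each stage assumes — NB counts with library-size
variation, coding/noncoding sequence composition, interval geometry,
spatially structured GWAS signal — so passing demonstrates that the
implementations are correct and calibrated under those assumptions. It
does not demonstrate robustness to what the generator omits: isoform
complexity and shared exons, GC/length biases, batch effects, linkage
disequilibrium among SNPs, or realistic QTL interval widths.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; pipeline runs with the same
configuration and seed produce byte-identical output tables, recorded
with md5 checksums in the JSON run manifest. The shipped validation uses
problem sizes chosen as a package design decision to keep the full suite
fast while retaining statistical resolution: 2,000 features for null
calibration of the DE test, 200 replicates for the GWAS null, 500
correlation pairs for the trans-target tail check, and the default
synthetic genome above for end-to-end recovery.

## Known limitations

- The NB test is a compact re-implementation: no outlier filtering, no
  fold-change shrinkage, and numerical agreement with other NB engines is
  not a goal (directional agreement on planted effects is).
- The modularity-scan tree cut is an approximation to dynamic tree cut;
  module *boundaries* can differ from the reference algorithm even when
  recovery is good.
- The duplex screen is a complementarity heuristic, not a free-energy
  model.
- The display transform `|log10(p + 1)|` compresses all enrichment
  signal into [0, log10 2]; use the plain `−log10 p` column for any
  quantitative reading.
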