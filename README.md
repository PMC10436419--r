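# lncmast

An R package implementing an end-to-end long noncoding RNA (lncRNA)
analysis pipeline for bovine subclinical-mastitis transcriptomics with
dietary intervention designs (four groups: subclinical-mastitis
folic-acid-fed **SF** and control **SC**, healthy fed **HF** and control
**HC**, with somatic cell count, SCC, as the health phenotype). It is
written for analysts who start from assembled transcripts
(StringTie/gffcompare-style GTF), per-sample read counts and public
genetic resources (QTL interval tables, GWAS summary statistics), and
want every stage of the lncRNA workflow as tested, scriptable functions.

## What it computes

- **lncRNA identification** — filter cascade on assembled transcripts:
  exon count ≥ 2 (known lncRNAs exempt), length ≥ 200 nt, read count > 0,
  class codes `i`/`u`/`x` for novel candidates and `=` matches to
  reference lncRNAs for known ones, then a strict-intersection
  coding-potential consensus over four built-in predictors: longest ORF
  (< 300 nt), Fickett TESTCODE (< 0.95), in-frame hexamer log-ratio
  (< 0), and a composite logistic score (< 0.5). Categories: `u` →
  lincRNA, `i` → ilncRNA, `x` → lncNAT.
- **Differential expression** — median-of-ratios size factors,
  negative-binomial Wald test with moment dispersion shrunk toward the
  across-feature trend, and the calling rule |log2FC| > 1 and p < 0.05
  (strict), with BH-adjusted p-values reported alongside and shared-DE
  intersection across the SF vs. SC and HF vs. HC comparisons.
- **Co-expression modules** — unsigned weighted network `|cor|^β` with β
  chosen by scale-free fit R² > 0.9, topological-overlap clustering,
  modularity-guided tree cut with kME refinement, module eigengenes
  (first PC) and eigengene–trait correlation.
- **Target prediction** — cis targets within ±100 kb of the lncRNA span
  (gap = `max(0, max(starts) − min(ends))`), trans targets by per-cohort
  Pearson |R| > 0.95 & p < 0.05, a simplified duplex-energy binding
  screen (ndG < −0.08), SCC regression of target genes, and the
  lncRNA–mRNA–pathway network.
- **Genetic integration** — lncRNA × QTL interval overlap at ±100 kb and
  sum-based GWAS signal enrichment: observed Σχ²₁ over SNPs within 50 kb
  of a gene set versus a random-gene-set permutation null, with empirical
  p = (1 + #{null ≥ obs})/(1 + n_perm).
- **Over-representation analysis** — one-sided hypergeometric tests of
  gene lists against GMT sets over the expressed-gene universe, BH
  corrected.
- **Synthetic data** — `simulate_dataset()` generates a fully
  ground-truthed input set (annotation, sequences, counts, phenotypes,
  QTLs, GWAS SNPs) with planted lncRNAs, DE features, modules, QTL hits
  and GWAS signal, so every stage can be scored for sensitivity,
  precision and calibration.

## Worked example

The package ships the worked-example tables it reproduces. Applying the
DE calling rule to the bundled per-comparison statistics of the shared
features:

```r
library(lncmast)

tab <- read.delim(example_table("shared_de_mrna"))
a <- call_de(data.frame(feature_id = tab$feature_id,
                        log2fc = tab$log2fc_SFvsSC,
                        pvalue = tab$pvalue_SFvsSC))
b <- call_de(data.frame(feature_id = tab$feature_id,
                        log2fc = tab$log2fc_HFvsHC,
                        pvalue = tab$pvalue_HFvsHC))
nrow(shared_de(a, b))
#> [1] 15
```

and the ±100 kb rule to the bundled lncRNA/QTL coordinate pairs:

```r
tab <- read.delim(example_table("lncrna_qtl_pairs"),
                  colClasses = c(chrom = "character"))
lnc <- unique(data.frame(transcript_id = tab$transcript_id,
                         chrom = tab$chrom, start = tab$lnc_start,
                         end = tab$lnc_end))
qtl <- data.frame(chrom = tab$chrom, start = tab$qtl_start,
                  end = tab$qtl_end, trait = tab$qtl_trait,
                  qtl_id = as.character(tab$qtl_id))
ov <- qtl_overlap(lnc, qtl, window = 100000)
c(rows = nrow(ov), lncRNAs = length(unique(ov$transcript_id)))
#> rows lncRNAs
#>   12      11
```

All 12 pairs pass (e.g. MSTRG.11108.1 at a 35,090 bp gap from its somatic
cell score QTL), involving 11 distinct lncRNAs.

The full synthetic demonstration generates a dataset, runs every stage on
the written files, and scores the results against the generator's ground
truth:

```r
demo <- run_demo(seed = 1)
round(demo$metrics, 3)
#> identify_sensitivity    identify_precision de_sensitivity_SFvsSC
#>                0.990                 1.000                 1.000
#>        de_fdr_SFvsSC de_sensitivity_HFvsHC         de_fdr_HFvsHC
#>                0.055                 1.000                 0.071
#>       de_sensitivity                de_fdr            module_ari
#>                1.000                 0.063                 0.915
#>     qtl_hit_recovery        gwas_scs_emp_p
#>                1.000                 0.002
```

i.e. 99% of planted lncRNAs are recovered with no false catalog entries,
all planted |log2FC| ≥ 2 effects are called with pooled empirical FDR
6.3%, module recovery reaches adjusted Rand index 0.91, all planted QTL
hits survive the overlap screen, and the planted GWAS-enriched gene set
is flagged at empirical p = 0.002.

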