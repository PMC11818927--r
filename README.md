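# perinatmir

Analysis of microRNA expression across tissues around birth, with a
synthetic small RNA-seq generator for end-to-end testing.

Newborn mammals must switch, within hours, from placental supply to
self-sustained physiology — gluconeogenesis in the liver, independent
breathing in the lung, regenerative growth in the heart. miRNAs (~22-nt
regulators that repress mRNAs through 3'UTR seed sites) are candidate
drivers of this transition. `perinatmir` implements the complete analysis
such a study runs over six tissues (heart, liver, spleen, lung, muscle,
duodenum) sampled prenatally and postnatally:

* **Quantification** — adapter trimming, quality/length filtering, read
  collapsing, direct assignment to mature sequences, the detection filter
  (count ≥ 3 in ≥ 1 sample), RPM normalization.
* **Annotation** — known / conserved / novel classes (exact match vs
  seed match to another species), 5p/3p arm census, genomic context of
  precursors (intronic / intergenic / exonic / intron–exon).
* **Expression structure** — Pearson correlation among samples, PCA,
  hierarchical clustering on 1 − r.
* **Tissue specificity** — TSI = Σᵢ(1 − xᵢ/x_max)/(N−1) with calls at
  < 0.15 (housekeeping) and > 0.85 (tissue-specific), and the
  Jensen–Shannon score TSS_t = 1 − √JSD(p, e_t) for assigning the specific
  tissue; three TSI variants (prenatal / postnatal / combined).
* **Differential expression** — TMM normalization, conditional-likelihood
  NB dispersion estimation, the exact conditional negative-binomial test,
  BH correction, and the rule fold change > 1.5 with FDR < 0.05
  (postnatal vs prenatal, per tissue).
* **Cross-tissue and targets** — overlap distribution of DE miRNAs across
  tissues, direction conservation, chi-square for DE × specificity,
  canonical seed-site prediction (8mer / 7mer-m8 / 7mer-A1), hypergeometric
  gene-set enrichment over GMT collections, and the anti-correlated
  miRNA–mRNA network.
* **Assay statistics** — 2^−ΔΔCt relative qPCR quantification,
  dual-luciferase normalization, protein-normalized glucose production,
  t-test / one-way ANOVA comparisons.

Because raw sequencing data for such designs is rarely portable, the
package ships a first-class synthetic generator (`synthetic_config()`,
`generate_reference()`, `simulate_counts()`, `synthesize_reads()`,
`simulate_assays()`) that emulates the study design — 35 libraries (one
postnatal spleen replicate dropped), NB counts with tissue-dominance and
stage effects, planted seed sites including the AKT3 wild-type/mutant
3'UTR fragments — and returns truth tables so every stage is testable as a
recovery problem.

## Worked example

```r
library(perinatmir)

cfg <- synthetic_config(seed = 7, n_mirnas = 120,
                        libsize_range = c(20000, 40000))
report <- run_pipeline(cfg)
print(report)
#> perinatmir pipeline report
#>   samples: 35; miRNAs detected: 120 of 120 simulated
#>   DE events: 13 (unique miRNAs: 12); network edges: 27
#>   DE recall 0.68, precision 1.00; tissue assignment accuracy 0.94
```

35 samples were simulated, quantified from synthetic FASTQ and filtered;
13 miRNA×tissue pairs passed FC > 1.5 at FDR < 0.05, all of them planted
(precision 1.00), recovering 68% of the planted fold changes (those near
the bottom of the 2–8× range at shallow depth are genuinely undetectable);
94% of truly tissue-specific miRNAs were assigned their true tissue by
maximum TSS. Census tables carry the percentage conventions of the field:

```r
report$tables$contexts
#>       context  n percent
#> 1    intronic 41   52.56
#> 2  intergenic 26   33.33
#> 3      exonic  0       0
#> 4 intron_exon 11    14.1
```

The liver anchor example — miR-22-3p targeting the AKT3 3'UTR — runs on
the published fragment sequences bundled as constants:

```r
predict_targets(c("ssc-miR-22-3p" = MIR22_3P), c(AKT3 = AKT3_UTR_WT))
#>           mirna gene start0 site_type
#> 1 ssc-miR-22-3p AKT3     28      8mer
predict_targets(c("ssc-miR-22-3p" = MIR22_3P), c(AKT3 = AKT3_UTR_MUT))
#> [1] mirna     gene      start0    site_type   <0 rows>
```

## Analysis workflow

The numbered scripts under `analysis/` run one full study emulation and
write small summary tables to `results/` (bulky intermediates go to
`scratch/`):

```sh
Rscript analysis/01_simulate_data.R      # references, counts, reads, assays
Rscript analysis/02_quantify.R           # FASTQ -> filtered count matrix
Rscript analysis/03_annotate.R           # classes, arm census, contexts
Rscript analysis/04_expression_profiles.R
Rscript analysis/05_specificity.R
Rscript analysis/06_differential_expression.R
Rscript analysis/07_targets_network.R
Rscript analysis/08_assays.R
Rscript analysis/09_report.R             # orchestrated end-to-end report
```

## Methods

See the methods vignette
(`vignettes/perinatal-mirna-methods.Rmd`) for the statistical model, the
formula choices (TSI/TSS variants, the conditional NB test and its
documented simplifications), numerical conventions, and what the synthetic
data does and does not demonstrate.
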