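---
title: "Methods: perinatal tissue miRNA analysis on synthetic small RNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perinatal tissue miRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perinatmir)
```

# Scope and model

`perinatmir` implements a desk-scale analysis of microRNA expression across
six piglet tissues (heart, liver, spleen, lung, muscle, duodenum) sampled
just before and just after birth, together with a synthetic data generator
that stands in for the sequencing and wet-lab assay data such a study
produces. Every stage — quantification, annotation, specificity scoring,
differential expression, target/network inference, assay statistics — is a
tested package function; the numbered scripts under `analysis/` narrate one
full run.

The generator is the study-design anchor. Its defaults encode the design the
analysis assumes: 6 tissues x 2 stages (prenatal/postnatal) x 3 replicates,
with one postnatal spleen replicate dropped for RNA quality, i.e. 35
libraries (18 prenatal, 17 postnatal). Reference size (300 mature miRNAs)
and depth (30–60k reads per sample) are deliberately desk-scale so the whole
workflow, tests included, runs in minutes on one CPU; both are configurable.

# The synthetic data generator

## Generative model for counts

Counts for miRNA $m$ in sample $s$ are negative binomial,
$y_{ms} \sim \mathrm{NB}(\mu_{ms}, \phi)$ with variance
$\mu + \phi\mu^2$ and default dispersion $\phi = 0.1$ (a typical
biological-replicate value for bulk count data; $\phi = 0$ switches to the
Poisson limit). The mean combines

* a per-miRNA baseline abundance, log-normal (sdlog 1.3) and normalized to
  proportions so a sample's expected depth equals its drawn library size;
* a **dominance multiplier** (default 10x) in one designated tissue for the
  fraction of miRNAs marked tissue-specific (default 0.583, matching the
  specific fraction the full-scale study reports);
* a **stage multiplier** $2^{\log_2\!FC}$ applied to postnatal samples of
  tissues where the miRNA is truly differentially expressed. True fold
  changes are drawn log-uniformly from the `fc_range` interval (default
  2–8, safely above the 1.5 calling threshold) with random sign, for a
  per-tissue fraction `frac_de` (default 0.025) of miRNAs.

All planted assignments are returned as truth tables so recovery is
checkable. When a "known" slot exists, the generator always includes
miR-22-3p as a known miRNA, marks it truly upregulated in postnatal liver
(log2 2.8), and embeds the canonical 8mer site for its seed in the AKT3
3'UTR — giving the pipeline a fully worked liver/gluconeogenesis example.
A separate UTR entry carrying the seed-site-mutated fragment is included as
a synthetic negative control.

## References, classes and genomic placement

Mature sequences are 19–26 nt with the length distribution peaking at 22 nt
(38%) and 76% of mass on 21–24 nt, mirroring typical clean small-RNA data.
Each mature receives a unique seed (positions 2–8) so class labels are
unambiguous by construction: *known* miRNAs are copied verbatim into a
same-species reference; *conserved* miRNAs get an other-species reference
entry sharing the seed but not the full sequence; *novel* miRNAs match
nothing. Class proportions default to 444:697:370 (the full-scale study's
Table-1 ratios) and are realized exactly up to largest-remainder rounding
(±1).

Hairpins are flank + 5p arm + loop + 3p arm + flank (60–120 nt; each mature
an exact substring), with arm usage (5p-only / 3p-only / both) drawn at the
study's 203:228:540 ratios. Precursors are placed on a virtual chromosome
against generated multi-exon gene models according to `context_props`
(default 516:319:1:135 for intronic : intergenic : exonic : intron-exon),
again exact to ±1.

## Reads and assays

Each synthetic read is the mature sequence (DNA alphabet) followed by the 3'
adapter, padded with random bases to 50 nt; qualities are constant Q40. A
configurable junk fraction (default 2%) of adapter dimers and sub-18-nt
inserts is appended and reported. There is no sequencing-error model by
default (`error_rate = 0`); the quantifier matches exactly, so the
noise-free round trip (synthesize, then quantify) reproduces the generating
counts identically — a core invariant of the test suite.

Assay tables are built by inverse construction so the downstream statistics
recover the programmed effects: Ct values are
$Ct_{ref} + base - \log_2(\text{expression}) + \varepsilon$, luciferase
wells carry programmed mimic/control activity ratios (default Wt 0.55, Mut
1.0), glucose wells carry per-well protein content, and the blood-glucose
time series interpolates the reported perinatal trajectory (6.03 mmol/L at
birth, 1.23 mmol/L nadir at 3 h, 2.23 mmol/L at 6 h) with a power-law fall
and rebound.

## Randomness

One config seed drives everything. Each generator stage seeds the RNG with
a fixed offset of it (reference +0, counts +1, reads +2, assays +3), so
artifacts are byte-reproducible independently of the order in which stages
are invoked — a slightly stronger guarantee than a single shared stream.

# Quantification

Small-RNA quantification is deliberately alignment-free: reads are trimmed
(earliest full-adapter occurrence, else the longest ≥5-nt adapter-prefix
suffix), filtered to an 18–26 nt insert window and mean quality ≥ Q20
(Phred+33), collapsed, and matched directly against the mature reference.
The window default reflects clean-read concentration at 21–24 nt; the exact
bounds are configurable. An insert matching exactly one mature sequence
contributes its multiplicity; inserts matching several (identical matures)
are discarded and tallied as ambiguous — deterministic and conservative —
and everything else counts as unmatched, so
assigned + ambiguous + unmatched equals the clean-read total. An optional
3'-tolerance accepts trimmed or hairpin-templated extended isomiR variants
(±t nt at the 3' end). Genome alignment and hairpin discovery are out of
scope; at this scale direct mature matching preserves the count semantics
the downstream statistics need.

The detection filter keeps miRNAs with count ≥ 3 in ≥ 1 sample. RPM
normalization divides by the library size — defined as the per-sample
assigned total, so RPM columns sum to $10^6$.

# Annotation

The seed is fixed at positions 2–8 (1-based) of the mature sequence; the
window is configurable since conventions vary. Classification precedence is
known (exact same-species match) > conserved (seed match to another
species) > novel. Genomic context ignores strand (an intronic miRNA is
conventionally called intronic whichever strand hosts it) and works on
0-based half-open intervals internally, converting to 1-based inclusive
GFF-style coordinates only on disk. A precursor overlapping no gene span is
intergenic; within a gene it is exonic, intronic, or intron–exon according
to which features it touches; across multiple genes the per-gene calls
combine with priority intron_exon > exonic > intronic. The per-base
membership oracle in the test suite pins this logic down exhaustively.

# Specificity scores

Neither the tissue-specificity index nor the entropy-based specificity
score has a single printed formula in the applied literature, so the
standard forms are adopted, documented, and isolated in one module so
alternates can be swapped:

* **TSI** (Yanai-style): $\mathrm{TSI} = \sum_i (1 - x_i/x_{max})/(N-1)$
  over per-tissue mean expression; 0 for uniform, 1 for single-tissue.
* **TSS** (Jensen–Shannon): $\mathrm{TSS}_t = 1 - \sqrt{\mathrm{JSD}(p,
  e_t)}$ with base-2 logarithms, $p$ the profile normalized to sum 1 and
  $e_t$ the one-tissue indicator; equals 1 iff expression is confined to
  tissue $t$.

Expression enters TSI as per-tissue mean RPM without log or pseudocount
(both metrics are scale-invariant in the relevant sense; a log2(RPM+1)
option exists). Calls use TSI < 0.15 for housekeeping and TSI > 0.85 for
tissue-specific, boundaries falling to the nonspecific middle band; the
specific tissue is the TSS argmax, ties broken to the lexicographically
smallest name. Three TSI variants are computed per miRNA — prenatal-only
(18 samples), postnatal-only (17), combined (35) — to check stage
robustness.

# Differential expression

Per tissue, postnatal vs prenatal: TMM normalization, conditional-likelihood
dispersion estimation, an exact conditional NB test, BH correction across
miRNAs within the tissue (the comparison is per-tissue, so no cross-tissue
correction), and the decision rule fold change > 1.5 (either direction,
strict) and FDR < 0.05 (strict).

The internals follow the quantile-adjusted conditional maximum-likelihood
approach with two deliberate simplifications, both documented in the code:
pseudo-counts equalize library sizes by scaling every sample to the
geometric-mean effective library (the conditional likelihood tolerates the
resulting non-integer counts; group sums are rounded only for the exact
enumeration), and tagwise dispersion maximizes the per-gene conditional
likelihood plus a fixed prior weight (10) times the average likelihood.
Numerical identity with any particular implementation is not a goal;
calibration and recovery are. The test suite checks a null false-positive
rate inside [0.03, 0.07] at 2000 genes, ≥80% recall with ≤10% empirical FDR
at |FC| = 4 over ten simulations, agreement of the φ = 0 path with direct
binomial enumeration to 1e-9, and TMM factor agreement with an independent
implementation.

Fold changes are generalized: group means of normalized counts with a 0.5
pseudo-count before the log ratio, which keeps zero-heavy miRNAs finite.
The n = 2 postnatal spleen group runs through the same machinery with a
logged warning.

# Targets, network and enrichment

Target prediction is canonical seed matching only: 7mer-m8 (reverse
complement of positions 2–8), 7mer-A1 (reverse complement of 2–7 followed
by A), 8mer (both), scanned on the given strand with no G:U wobble and no
3'-supplementary pairing; overlapping matches report the strongest class.
Context-style scoring is intentionally not reproduced. On the wild-type
AKT3 3'UTR fragment the scan yields exactly one 8mer for miR-22-3p and
nothing on the mutated fragment.

The network joins a DE miRNA to a predicted target when the gene moved in
the opposite direction in the same tissue (repression logic). Gene-set
enrichment is a one-sided hypergeometric over-representation test against
caller-supplied GMT collections with BH across sets — replacing external
annotation services with a self-contained equivalent whose p-values are
checked against exhaustive enumeration for small universes.

The chi-square for DE x tissue-specific association uses 1 df without
continuity correction. "Direction-conserved" requires DE in ≥2 tissues with
a single direction everywhere DE.

# Assay statistics

$2^{-\Delta\Delta Ct}$ uses the group-mean calibrator (ΔΔCt = ΔCt − mean
calibrator ΔCt), fixed efficiency 2, so the calibrator's geometric mean is
exactly 1. Luciferase activity is firefly/Renilla normalized to the same
construct's mimic-control mean. Glucose production normalizes by per-well
protein. Two-group comparisons use the pooled-variance t-test (the
conventional reading of the methods; Welch is a switch away), more groups
one-way ANOVA; flags are * for p < 0.05 and ** for p < 0.01. For two groups
F = t² holds to numerical precision.

# Numerical and formatting choices

* Percentages in census tables: 100·num/den rounded half-up to 2 decimals,
  trailing zeros trimmed ("53.14", "13.9", "0.1").
* PCA: SVD of the column-centered sample matrix (samples as observations)
  on z-scored log2(RPM+1); variance fractions are non-increasing and sum
  to 1.
* Hierarchical clustering: average linkage on 1 − Pearson by default.
* Degenerate inputs: all-zero profiles give NA TSI/TSS; all-zero genes give
  p = 1; zero library sizes, empty adapters, singleton assay groups, and
  malformed intervals raise early, named errors.

# What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis assumes —
NB counts with tissue and stage effects, planted seed sites, invertible
assay constructions — so green tests demonstrate that the machinery
recovers known truth under that model. It does not emulate sequencing
error profiles, isomiR edits beyond 3' trimming, genome-scale references,
multi-mapping ambiguity beyond identical matures, or annotation databases;
conclusions about real libraries therefore rest on the methods' published
behavior, not on these tests. Printed full-scale results that depend on the
original raw data (read totals, PCA fractions, specific DE identities,
enrichment p-values) are treated as context, not as reproduction targets;
the package's own checks are the census arithmetic, the statistical
calibration/recovery properties, and the worked AKT3/miR-22-3p example.

# Problem sizes

Defaults used by the analysis scripts and acceptance checks: 300 miRNAs x
35 samples at 30–60k reads per sample for the study emulation; 2000 genes x
6 samples for null calibration; 200 genes x 10 replicate simulations for
power; universes ≤ 25 for enumeration checks. These sizes were chosen so a
complete run stays within minutes on a single CPU while keeping every
statistical check well-powered.
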