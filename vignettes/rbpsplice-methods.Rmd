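---
title: "Models and methods behind rbpsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rbpsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpsplice)
```

# Overview

`rbpsplice` implements a desk-scale version of a common experimental design
for discovering splicing targets of an RNA-binding protein (RBP):

1. **Where does the protein bind?** RIP-seq counts over introns that flank
   alternatively spliced exons, compared between an IP and a control IP
   library.
2. **What changes when the protein is removed?** Differential relative exon
   usage between control and knockdown RNA-seq count profiles.
3. **Candidates** are genes with evidence on both tracks.

Two companion analyses round out the toolkit: the minimum-p log-rank
cutpoint scan used to dichotomize cohorts by a biomarker's expression, and
the classification of stable-isotope mass-isotopologue distributions (MIDs)
into reductive versus oxidative glutamine metabolism. A synthetic-data
module generates every input with planted ground truth, which is how the
package tests itself end to end.

The motivating biological example used throughout is the glutaminase gene
*GLS*: 19 exons, with two isoforms that share exons 1–14 and then diverge —
GAC includes exon 15 and terminates, while KGA skips exon 15 and includes
exons 16–19. The intron between exons 14 and 15 ("intron 14") is the
upstream flanking intron of alternative exon 15, and is the canonical
positive control for the atlas construction. A deterministic GLS-like
fixture ships in `inst/extdata/`.

# The annotation atlas

## Transcript filters

`apply_transcript_filters()` applies three rules, in a fixed order that is
part of the method's definition (changing the order changes the result):

1. transcripts without a CCDS entry are removed (version suffixes `.N` are
   stripped from both sides before matching);
2. genes left with fewer than two transcripts are removed — with one
   isoform there is nothing to compare;
3. genes whose remaining transcripts differ **only** at the 5′ boundary of
   the first exon are removed: transcriptional-start-site variation carries
   no splicing signal.

The filter is idempotent and may legitimately empty a catalog.

## Exon classification and intron atlas

Exon identity is the exact `(chrom, start, end)` key. An exon is
*constitutive* when its exact key occurs in every retained transcript of
the gene, *alternative* otherwise. Exact matching is a deliberate choice:
it is the only tolerance-free, reproducible reading, and it makes
alternative 5′/3′ splice-site variants register as alternative (two
overlapping-but-unequal exons are simply two distinct alternative exons).
Terminal exons that differ in their outer boundary also register, which is
required for KGA/GAC-style terminal divergence to be detected at all.

For every alternative exon the atlas records:

* per transcript **containing** the exon, its immediate upstream and
  downstream flanking introns (labels are strand-aware, i.e. in
  transcription orientation);
* per transcript **skipping** the exon, the single intron spanning the exon
  locus between that transcript's neighboring exons, labeled `spanning`.

Including the skipping intron matters: GLS intron 14 is simultaneously the
upstream flank of exon 15 (in the GAC path) and part of the exon-skipping
KGA path, so a flanks-only reading would under-represent exactly the kind
of interval the method is built to find. `flanks_only = TRUE` preserves the
narrower reading for comparison. Introns are deduplicated by exact key;
zero-length gaps between adjacent exons are skipped with a warning.
Coordinates are 0-based half-open internally and in the BED export; GTF
input is converted on parse.

# RIP-seq enrichment

## Pseudo-replicates

RIP-seq designs frequently lack biological replicates. The package follows
the bootstrap-style subsampling idea: each library column is expanded into
`B` *pseudo-replicates*, each an independent binomial thinning of the
original counts at rate `fraction` (defaults `B = 3`, `fraction = 0.8`).
Thinning per feature is distribution-equivalent to subsampling the
underlying reads without carrying read identities. Each stream is seeded
deterministically from `(seed, library_id, b)`, so results do not depend on
column order.

Pseudo-replicates measure sampling noise, not biological variability; the
resulting test is therefore anti-conservative relative to a replicated
design, which is the main reason the downstream caller also applies a
fold-change filter (below).

## The simplified NB Wald test

The published analyses this design emulates run DESeq2 on the
pseudo-replicated counts. `test_enrichment()` deliberately replaces the
full GLM machinery (shrinkage, outlier handling, dispersion trend) with a
transparent, closed-form negative-binomial Wald test so every number it
produces can be checked against a hand computation:

* normalization by median-of-ratios size factors (`estimate_size_factors`);
* per-arm means of normalized counts; per-intron NB dispersion
  (variance = μ + αμ²) by method of moments on the replicate spread, pooled
  across arms and floored at 1e-8;
* Wald statistic on the log2 fold change with a delta-method standard
  error; two-sided normal p; BH adjustment across all tested introns.

Numerical edge rules: introns with zero counts in both arms report p = 1
and log2FC = 0; when exactly one arm is all-zero its mean is floored, for
the statistic only, at the smallest observable normalized mean
(0.5 / (n·mean sf)). The *displayed* `log2_fold_change` adds a 0.5
pseudocount to each arm mean so it is always finite; the statistic never
uses a pseudocount. `call_bound()` applies the strict thresholds
fold > 3 and q < 0.05.

# Differential exon usage

Relative usage of exon *e* in sample *s* is its count divided by its gene's
total. `test_differential_usage()` compares exon-versus-rest-of-gene counts
between conditions with a quasi-binomial score statistic: pooled
condition-level proportions, binomial score variance inflated by a
dispersion factor estimated from the replicate-level Pearson spread and
floored at 1 (never deflated below binomial). This replaces a per-exon NB
GLM analysis with a closed-form test that preserves the relative-usage
estimand and is oracle-testable; the replacement is intentional and
documented rather than an approximation of the GLM's output.

The reported `log2_usage_ratio` is the exon-versus-rest (odds) ratio of the
knockdown over the control. For one perturbed exon per gene this equals the
planted usage factor exactly, whereas the plain proportion ratio also
absorbs the change the perturbed exon induces in its own denominator; for
small usage values the two coincide. Genes with a zero total in any sample
are excluded from testing and flagged.

# Candidate calling

`intersect_candidates()` lists genes owning at least one called bound
intron **and** at least one called differential exon, in deterministic
lexicographic order. `overlap_significance()` supplies an exact
hypergeometric tail p for the overlap; the universe is the genes that
survived the transcript filters, because only those genes could have been
called on either track.

# Survival cutpoint scan

`scan_cutpoints()` implements biomarker cutoff optimization: candidate cuts
are midpoints between consecutive sorted unique expression values (a cut
can never split ties), each cut is scored with the standard
one-degree-of-freedom log-rank test (ties handled in one hypergeometric
risk-set step), and the cut with the smallest p wins, ties broken toward
the lower cut. Cuts leaving a group below `ceiling(min_group_frac × n)`
are skipped; the default `min_group_frac = 0.1` avoids unstable
1-versus-(n−1) splits, and `min_group_frac = 0` restores the literal
all-possible-cutoffs scan.

The minimum p is reported unadjusted, matching common practice — and it is
**known to be anti-conservative**: under a true null the scan rejects far
more than 5% of the time at nominal 0.05 because it selects the best of
many correlated tests. The package both demonstrates this inflation in its
test suite and provides the remedy: `permutation_adjust()` recomputes the
full scan on cohorts with expression permuted against (time, event) and
reports the exact permutation p-value `(1 + #{min_p* ≤ min_p}) / (n_perm + 1)`.

# Isotopologue attribution

For U-¹³C₅/¹⁵N₂-glutamine tracing, mass shifts are total (carbons plus
nitrogens; e.g. aspartate m+5 = 4 carbons + 1 nitrogen). The frozen default
attribution table classifies: citrate m+5 reductive / m+4 oxidative;
fumarate and malate m+3 reductive / m+4 and m+2 oxidative; aspartate m+3
reductive / m+4 and m+5 oxidative; glutamate m+6 and α-ketoglutarate m+5 as
direct-precursor (shared) labels. m+0 is unlabeled; any other labeled shift
— including partially ¹⁵N-only shifts such as m+1 — defaults to shared
rather than being forced into a pathway. Succinate carries no
pathway-specific classes. `attribute_pathways()` sums fractions per class;
the four outputs always total 1. Natural-abundance correction is **not**
performed; callers may supply pre-corrected intensities. Group comparisons
use two-sided Welch t-tests with BH adjustment within a metabolite.

# The synthetic-data module

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed once and are not tuning knobs.

* **Annotation** (`simulate_annotation`): five structure classes (single
  isoform; cassette exon; terminal-divergent; TSS-only-varying; non-CCDS),
  laid out 50 genes per chromosome with 1 kb gaps; exons 80–300 bp,
  introns 200–1500 bp. `gls_like = TRUE` plants the full 19-exon GLS-like
  gene. The planted truth enumerates alternative exons and their
  flanking/skipping introns from construction knowledge, independently of
  the atlas code — the set-equality between the two is the module's
  primary acceptance property.
* **RIP counts** (`simulate_rip_counts`): per-intron base means are
  log-normal(log 50, 1) across introns — a realistic dynamic range —
  rescaled so a control library's expected column sum equals `depth`;
  counts are NB with a single dispersion α (mean–dispersion
  parameterization, variance μ + αμ², the DESeq-family convention),
  default α = 0.05. IP means are multiplied by the planted fold on bound
  introns only, so the raw IP:control ratio converges to the planted fold;
  the IP column's total consequently exceeds `depth` by the (small)
  enrichment mass, which median-of-ratios normalization absorbs.
* **Exon counts** (`simulate_exon_counts`): gene totals are NB with mean
  `depth`, split multinomially across exon bins — replicate-level
  expression noise is shared within a locus and cancels from relative
  usage, as it does for reads apportioned within a gene. Control split
  weights are log-normal(log 50, 1) times the number of transcripts
  containing the exon; knockdown weights multiply regulated exons by
  (1 − usage_shift) before renormalization.
* **Survival** (`simulate_survival_cohort`): standard-normal expression;
  exponential event times (baseline rate 0.1) with the hazard multiplied
  by the planted ratio above the planted expression quantile — the
  proportional-hazards effect is exact, so the hazard ratio is the planted
  parameter itself. Censoring is independent exponential with the rate
  solving the target baseline-arm censoring fraction; `censor_rate = 0`
  yields no censoring exactly.
* **MIDs** (`simulate_mid`): expected MID = (1 − labeled_fraction) at m+0
  plus the labeled mass split between the pure reductive signature shift
  and the oxidative signature shifts (equally, when there are two).
  `labeled_fraction` defaults to 0.35, consistent with a citrate control
  condition showing roughly 15% m+4 and 20% m+5. Noise is additive
  truncated Gaussian followed by renormalization, keeping every replicate
  on the simplex.

Every generator is a pure function of its parameters and seed.

## What the synthetic data does not emulate

Positional read biases, mappability, overlapping genes, multi-mapping,
isoform-level abundance shifts beyond single-exon regulation, real GENCODE
gene-structure complexity, batch effects, non-proportional hazards, and
isotope natural abundance. Passing the planted-truth suites therefore
demonstrates correctness of the algorithms under the stated models, not
performance on real sequencing data.

# Calibration expectations

The simplified NB Wald and quasi-binomial tests use plug-in
method-of-moments dispersions with a normal reference, so their null
p-values are approximately — not exactly — uniform; the package asserts
their calibration as bounds on call rates under planted nulls (call
fraction ≤ 0.1 at nominal FDR 0.05), not as exact uniformity. The
permutation-adjusted cutpoint p is exact by construction and is tested for
nominal rejection rates.

# Problem sizes used in the packaged checks

The test suite and `scripts/acceptance.R` run: 200-gene annotations over
10 seeds for atlas recovery; 1000-intron RIP panels with 5% bound introns
(20 null seeds at fold 1; 10 power seeds at fold 8, depth 10⁶);
100-cassette-gene usage panels over 20 seeds (shift 0.25, depth 10⁵ per
gene, 3 replicates); survival cohorts of n = 300 for cutpoint recovery
(50 seeds) and n = 120 for the 200-simulation null studies with 100
permutations each; and 10 end-to-end pipeline seeds at fold 8 /
shift 0.3 / depth 10⁶. These sizes give stable rate estimates while
keeping a full run in the low minutes on one CPU.

# Known limitations

* The enrichment test is not DESeq2 and will differ from it in detail
  (no shrinkage, no outlier handling); it preserves the statistical family
  and thresholds.
* The usage test collapses bootstrap replicate spread into one dispersion
  factor rather than combining per-replicate fits.
* Pseudo-replicates cannot recover true biological variance from a single
  library; claims from unreplicated designs remain weaker than replicated
  ones regardless of the statistics.
* The unadjusted minimum-p cut is reported for fidelity to common usage;
  for inference, use the permutation-adjusted p.
* MID attribution is a classification of labeled mass, not a flux model;
  fractional attributions are not flux estimates.
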