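---
title: "Methods: aneuploidy burden scoring, screen epistasis, and burden-stratified survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aneuploidy burden scoring, screen epistasis, and burden-stratified survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscope)
```

`aneuscope` implements the computational chain used to study net-gain
aneuploidy — the state of carrying more genomic material gained than lost —
in mammary epithelial cell models and cancer cohorts: copy-number burden
scoring from three input modalities, paired-clone CRISPR-screen epistasis
profiling with a chromosomal-location bias correction, burden–feature
association with gene-set enrichment, bioenergetics metric arithmetic, and
burden-stratified survival analysis. Every stage can be exercised on
synthetic data with planted truth, so the whole chain is testable without
any cohort download.

This vignette records the models, the parameters that matter, and the
design choices that were genuinely open.

## Aneuploidy burden from copy-number segments

The burden statistic is *gain − loss*: the genomic megabases affected by
called chromosomal gains minus those affected by losses. Samples with
positive net burden are classed `net_gain`, negative `net_loss`, zero
`balanced`.

Calling proceeds in three steps.

**Purity correction.** A tumor sample with purity $p$ observes a mixed
copy ratio $R_{obs} = p\,R_{tumor} + (1-p)$ on the linear scale, so we
de-mix with $R_{tumor} = (R_{obs} - (1-p))/p$ and report
$\log_2 R_{tumor}$. The cited purity-correction literature does not print
a formula; linear-scale de-mixing is the standard tumor/normal mixture
algebra and is the package's choice. Mixing and de-mixing on the linear
scale (not in log space) matches physical DNA mixing; the simulator uses
the same convention, which is why noise-free half-purity data score
identically to pure data after correction. Segments whose observed ratio
falls at or below the contamination floor $1-p$ have no positive tumor
ratio; they are flagged uncorrectable and excluded with a warning rather
than silently clamped.

**Arm calls.** An arm is called gained when the megabases covered by
segments with corrected $\log_2$ ratio above $+0.32$ reach at least 50% of
the arm length, and lost symmetrically below $-0.41$; if both directions
qualify the larger affected span wins, with an exact tie resolved to
neutral. The asymmetric cutoffs reflect that a single-copy loss moves the
$\log_2$ ratio further ($-0.41 \approx$ a loss at ~70% purity) than a
single-copy gain ($+0.32$).

**Weighting.** The quoted burden definition sums "megabases affected", so
the default (`weighting = "segment"`) sums the megabases actually meeting
the cutoff on each called arm. Whether the original cohort analysis summed
affected megabases or whole arm lengths is ambiguous; both conventions are
provided (`weighting = "arm"` counts full arm lengths), and the per-base
oracle tests cover both.

Coordinates are 1-based inclusive (SEG convention), so an arm spanning
`start..end` is `(end - start + 1)/1e6` Mb.

Gene-level matrices on the $\log_2(\text{copy ratio} + 1)$ scale (diploid
= 1.0) use the cutoffs $>1.16$ for gains and $<0.8$ for losses, counting
genes rather than megabases by default: gene-level input has no unique
megabase mapping unless gene lengths are supplied, in which case megabase
weighting is available. A matrix whose median is far from 1 triggers a
scale-mismatch warning, since these cutoffs are meaningless on other
scales.

Expression-based inference normalises each gene to the mean of a
non-tumor reference cohort, smooths along each chromosome with a centered
moving average (default 101 genes, odd-forced, shrunk with a warning on
short chromosomes), re-centers each sample to median 1, and calls gains
above 1.02 and losses below 0.98. This follows the logic of
reference-normalised expression CNA callers without reproducing any one
tool's internals; the window default trades arm-level sensitivity against
focal-event blurring, and edge genes use shrinking partial windows rather
than being dropped.

## CRISPR screen essentiality and epistasis

Screens compare guide abundance at zero (PD0) and six (PD6) population
doublings. Guide-level log2 fold changes are library-size normalised with
a pseudocount (default 0.5) so zero end-point counts remain finite, and
median-centered per clone so the non-targeting bulk sits at 0. Guides
below 30 reads at PD0 are flagged and excluded from testing: their fold
changes are dominated by sampling noise.

**Chromosomal-location bias correction.** Guides targeting copy-number-
altered arms show dropout/enrichment shifts unrelated to gene function.
The published analysis resolved this with a supplementary correction whose
detail is not in the main text, so the package defines its own explicit
scheme: for each CN-altered arm of a clone, subtract the arm's median
guide LFC minus the median over the clone's copy-neutral arms. The
neutral-arm reference (rather than the genome-wide median) matters when a
biased arm carries an appreciable fraction of the library, which would
otherwise drag the reference toward the bias. Only arms the karyotype
declares altered are touched — the correction deliberately never "fixes"
neutral arms, so true biology on neutral arms cannot be regressed away —
and arms with fewer than 20 guides are skipped because their median is
unstable.

**Gene-level testing.** Gene scores are the mean of their guides'
corrected LFCs (median available). Instead of re-implementing the
voom/edgeR machinery, significance comes from a self-contained permutation
scheme: the null distribution for a gene of $k$ guides is the score of
pseudo-genes assembled from $k$ guides drawn at random from the whole
library, two-sided p-values use the $(b+1)/(n_{perm}+1)$ correction, and
FDR is Benjamini–Hochberg. The default 10,000 permutations put the p-value
floor at $10^{-4}$; at least 1,000 are required for reported FDRs.
Essential-gene calls use FDR < 0.05 and LFC < −2.

**Epistasis.** The epistasis profile is the per-gene difference of mean
PD6 gene scores, aneuploid minus diploid, so negative values mean more
essential in the aneuploid background; swapping the groups negates it
exactly. With ≥2 clones per group, p-values come from permuting clone
labels (exhaustive when there are few label assignments — with 4 vs 3
clones there are only 35 — otherwise sampled); with single clones, from
per-gene two-sample permutation of guides between the clones.

**Pre-ranked GSEA.** The weighted Kolmogorov–Smirnov running sum walks the
ranking; hits increment by $|s|^p / \sum_{hits} |s|^p$ (default $p = 1$),
misses decrement by $1/(N - N_h)$, and ES is the maximum deviation.
Null ES values come from random same-size gene sets; the p-value is the
one-sided tail among same-signed null scores and NES divides ES by the
mean same-signed null magnitude. Sets are filtered to 5–500 members after
intersection; a set covering the whole ranking is degenerate ($N_h = N$
leaves no miss decrement) and is skipped.

## Feature association and normalisations

Feature–burden association is ordinary least squares (`feature ~ burden`),
exactly the `lm`-style analysis used for metabolite levels and gene-effect
scores against net-gain aneuploidy; robust alternatives are deliberately
omitted to mirror that choice. Two-sided p-values are BH-corrected across
all features of a matrix, and the slopes feed directly into
`preranked_gsea()`. Features are not log-transformed by default (the
upstream analysis is silent on this); callers can transform before
association. Burden with zero variance is rejected — the slope is
unidentifiable.

Abundance normalisations are deliberately plain arithmetic: per-ploidy
normalisation divides by `chromosome_count / 46` (the diploid baseline),
per-cell by the cell count, and label ratios (labeled::unlabeled UTP,
GSH::GSSG, ATP::AMP) are simple quotients with nonpositive denominators
reported as `NA`, never fabricated. Mitochondrial DNA copies per cell are
`ploidy × mt_coverage / autosomal_coverage`.

## Bioenergetics metrics

Extracellular-flux traces are summarised per phase as the mean of the last
3 measurement cycles (the instrument convention; configurable). For the
mitochondrial stress test (OCR phases basal, post-oligomycin, post-FCCP,
post-rotenone/antimycin A): nonmitochondrial respiration is the
post-rot/AA plateau, ATP-linked respiration is basal − post-oligomycin,
maximal respiration is post-FCCP − nonmito, and spare capacity is
maximal − basal mitochondrial. For the glycolytic rate test (PER):
compensatory glycolysis is post-rot/AA − post-2-DG. All metrics divide by
the per-well protein factor. Negative derived metrics (e.g. oligomycin
reading above basal) are flagged for QC but never clipped — clipping would
hide exactly the runs that need inspection.

## Survival stratification

Treatment classification lower-cases and trims each drug string and
matches it against the chemotherapy keyword list (`chemo_keywords()`).
Verbatim substring matching is unsafe for the short codes: "ac" is a
substring of "paclitaxel", a non-chemo taxane. The default therefore
token-matches keywords shorter than four characters or containing
non-letters ("ac", "tc", "tch", "5-fu") while longer keywords match as
substrings; `match = "substring"` reproduces the verbatim behaviour for
comparison. Patients with no drug strings are non-chemo and flagged
untreated.

Kaplan–Meier curves are the product-limit estimator with Greenwood
variance and the right-continuous step convention. The Cox model maximises
the Efron-tie partial likelihood by Newton–Raphson (step-damped; score
tolerance $10^{-9}$); Efron is the common default of the standard survival
software this replaces. When one group carries all events the partial
likelihood is monotone and the fit is reported as diverged with `hr = NA`
— a finite number there would be an artifact of the iteration cap.

The stratified analysis truncates follow-up at 5 years (administrative
censoring) before fitting, then estimates the net_loss-vs-net_gain hazard
ratio within chemo-treated and non-chemo patients plus per-stratum KM
curves. Whether the original cohort analysis truncated before fitting or
only plotted 5 years is not stated; truncation was chosen so the reported
hazard ratio describes the same window as the reported survival
probabilities, and the horizon is a parameter.

## The synthetic-data generator

The generator emulates the statistical structure each stage assumes, with
the study's printed design values as defaults:

* **Segments**: arm-level integer copy events on a diploid background,
  purity-mixed on the linear scale, Gaussian segment-mean noise. The
  default genome is a 10-arm toy (five chromosomes, 440 Mb total) so
  per-base oracles stay cheap; real cytoband tables load via
  `read_arm_table()`.
* **Screens**: negative-binomial counts with dispersion 0.1 (screen-like
  overdispersion; exactly Poisson at dispersion 0), 500 expected reads
  per guide emulating 500× representation, five guides per gene, planted
  essentials at LFC −2, and additive per-arm LFC shifts emulating the
  copy-number bias.
* **Features**: `slope × burden + Gaussian noise` per feature.
* **Survival**: exponential event times with the baseline arm calibrated
  through its 5-year survival ($\lambda = -\log S(5)/5$), a second arm at
  hazard ratio `true_hr`, administrative censoring at the horizon and
  optional uniform random dropout.
* **Expression**: genes on gained arms scaled by `dosage_effect` (losses
  by its inverse) against a flat reference, log-normal noise.

Identical seeds and parameters give byte-identical output, and every
planted event is recorded in a `sim_truth` object that exactly
parameterises the emitted data.

What the generator does *not* emulate — focal/sub-arm events, GC and
mappability waves, clonal heterogeneity, guide-efficacy variation,
off-target cutting, correlated metabolite blocks, non-proportional
hazards — bounds what passing tests show: they demonstrate that the
implementations recover the models they assume, not that those models
capture every property of real cohort data.

## Problem sizes and numerical choices

The test suite runs its recovery checks at reduced scale chosen to keep
the statistical claims meaningful: screen recovery at 2,000 genes × 5
guides with 1,000 permutations, burden oracles on a 100-base micro-genome
where exhaustive per-base counting is exact, Cox recovery on 2,000-subject
cohorts over 20 replicates, and GSEA enumeration on ≤8-gene toys where all
same-size subsets can be listed. The full 18,000 × 5 library is generated
once to check the reagent count. Tie-breaks are explicit throughout: equal
gain/loss span on an arm is neutral, permutation p-values never report 0,
and moving-average windows are forced odd so smoothing is centered.

## Reproducing the recovery results

`scripts/acceptance.R` regenerates the survival recovery quantities from
scratch (20 replicate cohorts each) and writes them as JSON; see the
README for the command line. The numbers it prints are computed at run
time by the same exported functions documented here.
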