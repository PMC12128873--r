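# aneuscope

Tumors are almost universally aneuploid, and most carry a *net gain* of
genomic material. Cells with supernumerary chromosomes face elevated
nucleotide, energetic and proteostatic demands, which makes net-gain
aneuploidy both a biological phenotype worth quantifying and a candidate
biomarker for response to DNA-damaging chemotherapy. `aneuscope` is an R
package for the computational chain that quantifies this phenotype and its
consequences:

* **Copy-number burden scoring** — purity-corrected arm-level gain/loss
  calls from SEG-style segment tables (loss below log2 ratio −0.41, gain
  above +0.32, with ≥50% of the arm affected), gene-level calls on the
  log2(copy ratio + 1) scale (loss < 0.8, gain > 1.16), and
  expression-inferred calls from reference-normalised, moving-average-
  smoothed modified expression (gain > 1.02, loss < 0.98). The burden
  statistic is **gain − loss**: megabases (or genes) affected by gains
  minus losses, with samples classed `net_gain` / `net_loss` / `balanced`.
* **CRISPR screen epistasis** — guide-level log2 fold changes between
  screen start (PD0) and end (PD6), a correction for the dropout bias of
  guides on copy-number-altered chromosome arms, permutation-based
  gene-level essentiality tests, aneuploid-vs-diploid epistasis profiles,
  and pre-ranked gene-set enrichment via the weighted Kolmogorov–Smirnov
  running sum.
* **Burden association** — OLS regression of any feature matrix
  (metabolite abundances, gene-effect scores) on burden, with BH FDR;
  ploidy- and per-cell normalisations and label-ratio metrics for tracing
  data; mitochondrial DNA copy estimation from coverage ratios.
* **Bioenergetics** — mitochondrial stress test and glycolytic rate test
  summary metrics (ATP-linked, maximal, spare, nonmitochondrial
  respiration; basal/compensatory/blocked glycolysis) from phase-averaged
  instrument traces.
* **Survival stratification** — chemotherapy classification from
  free-text drug names, hand-rolled Kaplan–Meier curves with Greenwood
  variance, Cox proportional hazards with Efron ties by Newton–Raphson,
  and the burden × treatment stratified analysis.
* **Synthetic data** — generators for every input above with planted,
  recorded truth (arm events mixed with purity, negative-binomial screen
  counts with planted essentials and arm biases, burden-coupled features,
  dosage-coupled expression, two-arm exponential survival cohorts), so
  the full pipeline runs and is tested without any external download.

## Worked example

Score burden from simulated segment data, then estimate the survival
contrast of a cohort generated with a known hazard ratio:

```r
library(aneuscope)

ev <- data.frame(sample   = c("t1", "t1", "t2"),
                 arm_id   = c("1q", "3p", "2q"),
                 direction = c("gain", "gain", "loss"))
sim <- simulate_segments(toy_genome(), ev, purity = 0.7,
                         noise_sd = 0.03, seed = 42)
score_segments(sim$segments, toy_genome())
#>   sample gain_mb loss_mb net_mb    class
#> 1     t1     100       0    100 net_gain
#> 2     t2       0      60    -60 net_loss
```

Sample `t1` gained the 70 Mb 1q arm and the 30 Mb 3p arm (100 Mb of net
gain); `t2` lost the 60 Mb 2q arm — both recovered through 70%-purity,
noisy segment means after purity correction.

```r
coh <- simulate_survival_cohort(2000, true_hr = 2.67,
                                baseline_5yr_survival = 0.95, seed = 42)
cox_hr(coh$cohort$time, coh$cohort$event, coh$cohort$group)
#> Cox fit: HR = 3.261 (coef 1.182, se 0.1733), Wald p = 9.1e-12, n = 2000, events = 181
#>   hazard of net_loss relative to net_gain

gain <- subset(coh$cohort, group == "net_gain")
km_at(km_curve(gain$time, gain$event), 5)
#> [1] 0.956
```

A single 2,000-patient cohort generated at hazard ratio 2.67 fits at
3.26 (within sampling noise of ~180 events; the mean over 20 replicate
cohorts lands on the generating value — see below), and the net-gain
arm's Kaplan–Meier 5-year survival recovers the generating 95%.

`run_pipeline(pipeline_config(), out_dir)` chains every stage —
simulate → score → screen → associate → survive — writing per-stage CSVs,
a log, and a `summary.json` with the config hash and seed; reruns with
the same config are bit-identical.

## Documentation

Every exported function carries roxygen documentation, and
`vignettes/aneuploidy-burden-methods.Rmd` describes the models,
thresholds, design decisions and the limits of what the synthetic-data
tests demonstrate.
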