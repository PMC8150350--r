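---
title: "PD-L1 scoring algorithms and tumor immune microenvironment phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PD-L1 scoring algorithms and tumor immune microenvironment phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1time)
```

## The problem

Three PD-L1 scoring algorithms gate access to immune checkpoint inhibitors
in urothelial cancer, and they do not measure the same thing. The combined
positive score (CPS, cut-off 10) counts PD-L1-positive tumor cells (TC)
and immune cells (IC) against viable tumor cells; the Ventana IC score
(cut-off 5%) measures the share of tumor area occupied by PD-L1-positive
IC; the TC~area~25%/IC~area~25% rule is positive when either compartment
reaches 25%. Applied to the same patients they produce overlapping but
distinct "PD-L1 positive" populations, and none of them maps cleanly onto
the spatially organized immune phenotypes of the tumor immune
microenvironment (TIME) that actually carry the prognostic signal. This
package implements the scoring algorithms, the phenotyping, and the
statistics needed to quantify that mismatch on tissue-microarray (TMA)
immune-profiling data from muscle-invasive bladder cancer (MIBC), together
with a synthetic-cohort generator that emulates the structure of the
motivating 193-patient study.

## Scoring and consensus

`compute_cps()` implements CPS = 100·(pos~TC~ + pos~IC~)/viable~TC~,
capped at 100 and undefined for an empty denominator. `build_consensus()`
takes per-assay readouts for the four companion diagnostic assays (SP142,
SP263, 22C3, 28-8) and forms per-patient medians to damp inter-assay and
section effects. Two choices deserve note:

* **SP142 exclusion.** SP142 systematically under-detects PD-L1 on tumor
  cells, so the TC-dependent consensus scores (`cps_consensus`,
  `tc_area_consensus`) are medians over SP263/22C3/28-8 only. IC detection
  is interchangeable across all four assays, so the IC consensus uses all
  four. A property test perturbs SP142's TC and CPS readouts at random and
  asserts the TC-dependent consensus scores never move.
* **Ventana IC vs IC~area~.** Both are the percentage of tumor area
  covered by PD-L1-positive IC; the motivating analysis carries them as
  two features. The package computes both by the same median-over-four
  rule and keeps them as separate columns so the clustering feature space
  matches. Collapsing them to one feature would change cluster geometry.

The even-count median is the mean of the middle pair, so every consensus
score is deterministic. Missing assays degrade to the median of whatever
eligible assays remain; only a patient with no eligible assay at all
yields a missing score (a warning, and a hard error at classification).
The durvalumab algorithm additionally contains an immune-cells-present
sub-rule at very low infiltration in its full label; the analysis this
package supports uses only the 25% TC-or-IC rule, which is what
`classify_pdl1()` implements. All three cut-offs are inclusive (≥),
matching the clinical convention of "CPS ≥ 10" etc.

## From densities to phenotypes

Inputs are positive-cell densities (cells/mm²) for CD3, CD8, FOXP3, CD56,
CD68, CTLA-4, LAG3, PD-1 and GZMB on up to four 1-mm TMA cores per patient
(two at the invasion front, two in the tumor center). Cores judged
non-representative (< 5% tumor area) or artefactual arrive flagged
`qc_pass = FALSE` and are dropped by `filter_qc()`; patients are excluded
only if they lose every core.

`aggregate_densities()` takes the per-(patient, marker, region) median
across cores. `transform_features()` maps densities through
x → log₂(x + 1) and Z-scores each feature with the population SD
(divisor n); the four PD-L1 consensus scores are Z-scored on their native
percent scale without the log. Numerical policies, each chosen for
determinism and robustness on sparse TMA data:

* **Pseudocount +1.** Zero densities are common (empty cores for rare
  markers); log₂(x+1) is monotone, bounded below, and maps 0 to 0. The
  pseudocount is a `transform_features()` argument.
* **Population SD.** Makes the two-patient case exact ({1, 3} → Z = ∓1)
  and is a one-line change to sample SD if preferred.
* **Zero-variance features** become all-zero columns rather than NaN.
* **Missing cells** (a patient with no qc-passing core for a
  marker/region) are imputed with the feature's cohort median before the
  Z-transform, which preserves exact Z-centring and adds minimal
  structure. A feature observed in no patient becomes a zero column.

The immune cell infiltration score (`compute_icis()`) is the arithmetic
mean of the 18 density Z-scores. The mean (rather than the sum) keeps the
score scale-free in the number of markers; since neither aggregation is
pinned down by the motivating description, the mean was chosen and the
cohort-mean-zero invariant is tested at 10⁻⁹. sTILs scoring is kept out of
the clustering features: it is an H&E-based estimate on a different
measurement scale, and the cluster space is defined by the IHC panel plus
PD-L1 consensus scores.

`wpgma_cluster()` performs agglomerative clustering with weighted average
linkage (WPGMA — `stats::hclust(method = "mcquitty")`) on Euclidean
distances between patient rows, cut to exactly k = 4 flat clusters
(k is an argument; 4 is the number of reproducible TIME phenotypes).
WPGMA is verified against an independently re-implemented brute-force
agglomeration on random small instances. Clustering is over patients only;
any feature-side ordering in heat-map displays is presentational.
`label_phenotypes()` then assigns labels deterministically: the cluster
with the highest mean Z of `tc_area_consensus` is `Evasion` (constitutive
TC expression); of the rest, the highest mean Z of `ic_area_consensus` is
`InflamedHigh`; the remaining two split by mean ICIS into `InflamedLow`
(higher) and `Uninflamed` (lower). Ties — possible only on degenerate
inputs — resolve toward the lower cluster id with a warning.

## Concordance, coverage, rescue

`venn_partition()` computes the exact 8-region partition of the three
binary statuses plus per-algorithm totals and the union; the regions
always sum to the cohort size, and the totals are cross-checked two ways
in tests. `overall_percentage_agreement()` is the fraction of concordant
cases; it is symmetric and invariant to consistently flipping the coding.
`phenotype_coverage()` cross-tabulates positivity against phenotype.
`rescue_inflamed_low()` restricts to `InflamedLow` patients negative by at
least one algorithm and flags those with CD8 ≥ 201 cells/mm² (patient
median across all qc-passing cores, regions pooled) or sTILs ≥ 10% — both
cut-offs are the motivating cohort's medians and are parameters, because
another cohort's medians will differ.

### Divergences the fixtures make explicit

The package ships two deterministic 193-patient fixtures built from the
motivating study's printed summary counts, used by the acceptance tests.

* `fixture_from_venn()` reproduces the printed Venn partition exactly
  (54/21/10/1/8/5/4/90, totals 84/70/89, union 103). The pairwise OPAs
  implied by this partition range from 77.2% to 88.1%, whereas the study
  prints an OPA range of 63.1–87.7%. The printed range is not recoverable
  from the printed partition under consensus-level statuses; it was
  plausibly computed per-assay rather than per-consensus. The package
  reports consensus-level OPA and leaves the discrepancy visible rather
  than forcing agreement.
* `fixture_crosstab()` encodes the phenotype-coverage and rescue counts.
  One printed combination is arithmetically impossible: among 48
  `InflamedLow` cases negative by at least one algorithm with all 48
  CPS10-negative, 46 Ventana-negative and 44 TC/IC-negative force at
  least 42 triple-negatives, yet 33 triple-negatives are printed. The
  fixture keeps the counts the analysis actually relies on (48 eligible,
  48 CPS10-negative, 46 Ventana-negative, 33 triple-negative, 39 rescued)
  and caps TC/IC-negatives at 35, the maximum consistent with the rest.

## Survival

`km_estimate()` (product-limit, events-first at ties), `survival_at()`
(right-continuous step function; five-year rates are read at 60 months,
months being the working time unit), `logrank_test()`,
`reverse_km_followup()` (event indicator inverted; median potential
follow-up, `NA` when not reached) and `cox_multivariable()` all delegate
the estimation to the `survival` package; the package's contract is the
covariate specification, ties handling (Efron — robust with monthly
granularity) and output schema. Hand-written product-limit, O−E and
partial-likelihood oracles in the test suite keep the checks independent
of that delegation. Cox models adjust for pT stage, pN stage,
lymphovascular invasion, age, gender, margin status, adjuvant
platinum-containing chemotherapy and grade; exact covariate encodings are
cohort-specific and therefore left to the caller's columns (the synthetic
generator uses pT2/3/4, pN0/pN+, L0/L1, R0/R1, G2/G3). Rows with missing
covariates are complete-case excluded with a reported count.

## The synthetic-data generator

`generate_cohort()` emulates the data structure the analysis assumes — it
is a study-conditions generator, not a fitted model of any real cohort:

* **Allocation.** Phenotype counts by largest-remainder rounding of the
  prevalences (default 0.14/0.14/0.35/0.37 for
  Evasion/InflamedHigh/InflamedLow/Uninflamed, matching the two printed
  n = 27 clusters at n = 193; the InflamedLow/Uninflamed split is an
  assumption and an argument).
* **Densities.** Per-core density 2^z − 1 with z ~ N(μ~marker,region~ +
  phenotype shift, 0.8), truncated at 0, so the log₂(x+1) feature
  transform recovers μ. Marker baselines follow typical urothelial
  infiltrates (CD3 densest, CD56 sparsest), the invasion front runs
  0.4 log₂ units denser than the tumor center, and the default phenotype
  shifts (+2.5/+0.8/0/−2.5 for InflamedHigh/Evasion/InflamedLow/
  Uninflamed) give clearly separated clusters — appropriate for a
  generator whose job is to define recoverable ground truth.
* **PD-L1.** A patient-level latent percent score (phenotype mean, SD 8)
  plus per-assay Gaussian noise (SD 5), clipped to [0, 100]; SP142's TC
  readout is multiplied by 1 − attenuation (default 0.8).
* **Survival.** Exponential per endpoint with rate λ = −log S₅ᵧ/60 solved
  from the phenotype's five-year rate (defaults: DSS
  0.298/0.747/0.431/0.277 — generator parameters, not claims about real
  data). The exponential is chosen for invertibility from a single
  five-year rate. Censoring is uniform on [0, b] with b solved per
  phenotype so the expected censored fraction hits the target (default
  0.3).

What the generator does **not** emulate: intra-core spatial
autocorrelation, inter-pathologist scoring variance, assay-specific IC
biases beyond SP142's TC attenuation, non-proportional hazards, and
covariate–outcome confounding (covariates are drawn independently of
survival, which is exactly what the Cox recovery study needs). Passing
tests on generated cohorts therefore demonstrate correctness of the
machinery and recoverability under the assumed structure, not performance
on real TMA data.

## Verification scale and interpretation

The test suite sizes were chosen to keep the full run under a minute while
leaving the statistical checks well-powered: WPGMA vs oracle on 50 random
instances (n ≤ 12); KM vs oracle on 100 random instances; five-year-rate
recovery on 20 × 5,000-patient cohorts; Cox hazard-ratio recovery (true
HR 0.5, two balanced phenotype arms at n = 2,000) over 20 seeds;
end-to-end phenotype recovery over 20 default cohorts. Two statistical
readings are deliberate:

* The five-year KM recovery bound (±3 percentage points) applies to the
  across-seed mean per phenotype. At ~700 patients per phenotype the KM
  estimate itself has sampling SD ≈ 2.2 points, so a per-seed bound at ±3
  would fail by ordinary Monte-Carlo error; the across-seed mean has
  Monte-Carlo SE ≈ 0.5 points, making the bound a genuine calibration
  check of generator plus estimator.
* Phenotype recovery (≥ 90%) is pooled across seeds. WPGMA occasionally
  isolates an extreme outlier as a singleton cluster, which costs one seed
  most of one phenotype; pooled recovery on defaults runs ≈ 96–98%.

## Known limitations

Image analysis (segmentation, density extraction) is upstream and out of
scope — densities are inputs. The rescue cut-offs and phenotype profiles
are cohort-calibrated defaults, not universal constants. Patient-level
consolidation of discordant duplicate-core PD-L1 ratings is assumed done
upstream: assay readouts enter at patient level. Proportional-hazards
diagnostics beyond non-convergence/separation errors, competing risks and
time-varying covariates are not provided.
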