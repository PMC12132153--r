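# isomiRSurv

Survival prognostication from cell-free isomiRs — miRNA sequence variants
(5′/3′ end shifts, trimmings, non-templated additions, internal
substitutions) circulating in plasma — for amyotrophic lateral sclerosis
(ALS) cohort studies. The package implements the complete analysis chain as
tested, reusable R functions, together with a synthetic two-cohort generator
so that every stage can be exercised and validated without access to patient
data. It is aimed at biostatisticians and computational biologists building
or auditing small-RNA prognostic-biomarker pipelines.

## What it implements

1. **Synthetic data** — a miRBase-style reference panel; small-RNA reads with
   3′ adapter (`TGGAATTCTCGGGTGCCAAGG`) and 12-nt UMIs plus ground truth; and
   a two-cohort generator: UMI counts `x_ij ~ NegBin(μ_j s_i b_{batch(i)},
   α)` with MCAR dropout, and survival times from an exponential
   proportional-hazards model `λ_i = λ_0 exp(η_i)` where planted isomiR
   effects and mild clinical effects (NfL, DeltaFRS, miR-181) enter `η_i`.
   The presets emulate a discovery cohort (n = 154, ~9% censoring) and a
   replication cohort (n = 200, ~54% censoring).
2. **IsomiR calling** — running-sum quality trimming (score `0.05 − p_err`
   per base, keep from the first positive running sum to its maximum),
   ambiguity trimming (longest window with ≤ 2 N), adapter trimming, 15–55 nt
   length filter, UMI extraction, alignment to mature references with end
   offsets in ±2 and ≤ 2 substitutions, uniform 1/k weight splitting across
   equally good assignments, UMI deduplication, and a round-tripping isomiR
   nomenclature (`isomiR-let-7g-5p.t`, `isomiR-146a-5p.T22A`, …).
3. **Preprocessing** — abundance filter (mean > 5 UMIs), multiple imputation
   (denoising autoencoder, or a deterministic median imputer), DESeq-style
   median-of-ratios size factors, restoration of original zeros,
   empirical-Bayes batch adjustment (ComBat), cross-cohort feature
   intersection and per-cohort standardization.
4. **Survival statistics** — Kaplan–Meier with median survival, Mantel–Cox
   log-rank, Cox PH (Breslow ties, Wald inference, Harrell C-index), BH-FDR,
   IPCW cumulative/dynamic AUC(t), median dichotomization with threshold
   transfer, an |log HR|-maximizing cutpoint optimizer with arm-size guard,
   ratio biomarkers, and the Schoenfeld-residual PH check.
5. **Feature selection** — bootstrap subsets with a per-feature coverage
   guarantee (reference scale: 1,480 features, subsets of 20, coverage ≥ 50,
   ≈ 3,700 subsets; 2²⁰ ≈ 10⁶ combinations per subset, ≈ 3.9 × 10⁹ overall),
   sequential forward selection under 10-fold cross-validated survival
   learners (Cox, random survival forest, gradient-boosted Cox), ≥ 90%
   frequency selection, a refinement round, and kneedle-style elbow
   thresholding of subset C-indexes.
6. **Explanation** — exact Shapley attributions for linear risk
   (`φ_ij = β_j (x_ij − x̄_j)`), a permutation Monte-Carlo estimator for
   arbitrary learners, and attribution-derived hazard ratios
   `HR_j = mean{exp(φ_ij) : x_ij > x̄_j} / mean{exp(φ_ij) : x_ij ≤ x̄_j}`.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `07_feature_views.R`); each stage reads the previous
stage's outputs under `results/` and prints what it found. Running stages
1–6 end to end:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

prints, among other output:

```
read-level ground-truth recovery: 100.00%
discovery: 1/106 isomiRs at FDR <= 0.05; 1 replicate at p <= 0.05
top marker isomiR-letA-5p.t: discovery log-rank chi2 = 17.50 (p = 2.9e-05),
  replication chi2 = 7.23 (p = 0.0072)
<selection_report> 107 subsets -> 5 survivors -> final panel of 5
```

and an attribution-derived hazard-ratio table whose planted marker row
(`isomiR-letA-5p.t`, HR ≈ 0.61 in both cohorts) recovers the effect the
generator planted (HR 0.6): the marker is found by the univariate screen,
survives threshold transfer into the held-out replication cohort, and is
selected by the ensemble.

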