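---
title: "Methods: isomiR-based survival prognostication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR-based survival prognostication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

isomiRSurv implements a discovery-to-replication prognostication analysis
for circulating isomiRs in ALS: calling isomiRs from small-RNA reads,
preprocessing UMI count matrices, univariate and multivariate survival
statistics, an ensemble feature-selection procedure, and Shapley-based model
explanation. This vignette records the models, the parameters that matter,
and the design decisions taken where the procedure leaves latitude. Every
number quoted here is computed by the package's test suite or analysis
scripts, not asserted from memory.

## The synthetic cohort generator

The generator stands in for plasma small-RNA sequencing of two ALS cohorts,
and its defaults are the study conditions the rest of the package is tested
under: a discovery cohort of 154 patients with a 9% censoring target and a
replication cohort of 200 patients with a 54% censoring target, library
batches capped at 48 samples (the index-kit constraint), a shared catalog of
isomiR features (default 1,480), and one planted prognostic marker,
`isomiR-letA-5p.t`, with hazard ratio 0.6 under the dichotomous mechanism
and a baseline mean abundance of 264 UMIs (the abundance scale of the
headline marker; with the default dispersion this puts the cohort median
near 250 UMIs).

**Counts.** Feature j in sample i is drawn
`x_ij ~ NegBin(mu_j * s_i * b_batch(i), alpha)` with per-feature log-normal
baseline means (meanlog `log(20)`, sdlog 1.3 — spanning the rare-to-abundant
range that survives a mean > 5 UMI filter), per-sample log-normal depth
(sdlog 0.3), multiplicative per-batch effects (sdlog 0.15), and dispersion
`alpha = 0.4` (`var = mu + alpha mu^2`). Dropout is
missing-completely-at-random (default rate 0.05); the true sparsity
mechanism of small-RNA detection is unknown, so the simplest mechanism that
exercises the imputation/zero-restoration contract was chosen.

**Survival.** Event times are exponential under proportional hazards,
`lambda_i = lambda_0 exp(eta_i)` with `lambda_0 = log(2) / median survival`
(13.9 and 14.7 months for the two cohort presets). The distribution family
is a free choice; exponential is the simplest PH-consistent generator, and
the Cox machinery downstream never uses the parametric form. `eta_i`
collects the planted isomiR effects — dichotomous (`log(hr)` for latent
count above the cohort median) or linear (`log(hr)` per standard deviation
of log1p count) — plus mild prognostic contributions from NfL, DeltaFRS,
and miR-181 (hazard ratios 1.6, 1.25, 1.4 per SD), so that the comparator
analyses (ratio biomarkers, multivariate models) have something real to
find. Note one consequence checked by the tests: with those clinical
channels active, the *marginal* hazard ratio of the planted marker is
attenuated relative to the planted conditional value, as in any
proportional-hazards model with omitted covariates.

**Censoring.** Censoring is the minimum of an administrative cutoff and an
exponential random-censoring time. Because the censoring fraction under
heterogeneous hazards is `E[c / (c + h_i)]`, the preset configurations
solve that expectation for `c` against the realized hazards (uniroot)
rather than using the homogeneous closed form `c = h q / (1 - q)`, which
would overshoot the target once planted and clinical effects widen the
hazard distribution.

**Clinical covariates** are drawn independently with marginals matching the
two cohorts' demographic tables (sex, age at onset/enrollment, ALSFRS-R,
DeltaFRS, onset site, riluzole); the joint correlation structure is not
modeled. What passing tests on these data do **not** show: robustness to
informative missingness, joint clinical correlations, sequencing error
profiles, adapter chimeras, or batch effects correlated with outcome.

## IsomiR calling

Reads pass, in order: quality trimming, ambiguity trimming, adapter
trimming, length filtering, UMI extraction, and reference assignment. The
order follows the processing narrative of the protocol being reproduced.

- **Quality trimming.** Per base, error `p = 10^(-Q/10)` and score
  `0.05 - p`; the running sum of scores is scanned and the region from its
  first positive value to its maximum is kept; reads whose running sum never
  becomes positive are rejected. One property worth stating precisely:
  raising the threshold (tolerating more error) can only extend the kept
  region, never shorten it — the tests assert this direction.
- **Ambiguity trimming** keeps the longest window with at most two `N`s,
  leftmost on ties (two-pointer scan; the tests compare against an
  exhaustive window enumeration).
- **Adapter trimming** requires either the full 21-mer
  `TGGAATTCTCGGGTGCCAAGG` (first occurrence) or an exact prefix of at least
  10 nt flush with the read's 3′ end; reads without a match are dropped.
  The tolerance is deliberately exact-match: deterministic and testable.
- **Synthetic read layout** is `insert + adapter + UMI(12 nt) + filler`;
  the UMI is read from the 12 bases following the adapter.
- **Assignment.** Candidate alignments place the insert on each mature
  reference with 5′/3′ end offsets in ±2 nt and at most two substitutions
  counted over the overlap; insert bases beyond either reference end are
  extension bases, not mismatches. True internal indels are not modeled —
  the operative constraints are the ±2 nt window and the ≤ 2 mismatch cap.
  Only the minimal-mismatch tier is kept ("equally well" = equal
  substitution count; offsets carry no penalty inside the window) and its k
  members get weight 1/k each.
- **UMI collapse.** Ties are split per read first, then deduplicated on
  distinct (UMI, isomiR) pairs, each pair contributing the weight of the
  first read that produced it. Whether tie-splitting precedes or follows
  deduplication is not fixed by the protocol; splitting first keeps
  per-molecule mass conserved when duplicate reads agree, which the tests
  verify.
- **Nomenclature.** Names follow a repo-defined grammar reproducing the
  published exemplars: substitution tokens `G9C` (1-based position on the
  observed sequence), `t`-runs for 3′ trimming, uppercase suffixes for
  templated 3′ extension, lowercase for non-templated addition, and `as`
  for alternative 5′ starts (bare `as` = +1; `as2`, `as-1` general). Two
  boundary rules keep the grammar unambiguous: a non-templated addition
  consisting only of `t` is unrepresentable (it would collide with the
  trimming token), and the caller, lacking hairpin context, labels
  extensions non-templated except all-T extensions, which render uppercase.
  `parse_isomir_name()` inverts `name_isomir()` for every representable
  record (200-case round-trip property test).

## Preprocessing

The chain is `raw -> filter -> impute -> size-normalize -> restore zeros ->
batch-adjust -> standardize`, enforced by a state flag; out-of-order calls
raise errors.

- **Abundance filter:** keep features with mean (missing counted as zero)
  strictly above 5 UMIs. The strict boundary is configurable. The filter is
  computed on raw counts before imputation, which is the reading most
  consistent with the stated motivation (geometric means cannot be computed
  on missing values, so imputation follows the filter).
- **Imputation** is a contract with two implementations: a denoising
  autoencoder (three hidden layers of 512, corruption probability 0.95,
  learning rate 1e-6, 40 training passes; imputed value = mean of 50
  dropout-active forward passes; clinical covariates age, sex, onset site,
  riluzole enter one-hot as auxiliary inputs) and a deterministic
  feature-median imputer used wherever determinism matters more than
  fidelity. Layer sizes and pass counts scale down in tests. A feature with
  no observed value falls back to the cohort-level observed median.
- **Size factors** are median-of-ratios: reference_j = geometric mean of
  feature j across samples (features containing zeros are excluded from the
  reference), factor_i = median over features of `x_ij / reference_j`,
  rescaled to geometric mean 1. The rescaling convention only fixes a
  global constant; the tests verify the formula against a literal
  re-implementation exactly and against the DESeq2 implementation to within
  its log-scale-median variant. One subtlety the tests pin down: because the
  reference is data-dependent, multiplying one sample by c changes all
  factors by a common constant times c for that sample — equivariance holds
  up to the geometric-mean-1 convention.
- **Zero restoration** sets originally missing cells back to zero after
  normalization, so imputed values influence only the size factors, not the
  downstream batch model.
- **Batch adjustment** is parametric empirical-Bayes location/scale
  adjustment (ComBat) with no covariates beyond batch. Zero-variance
  features pass through unchanged. EB shrinkage removes the *systematic*
  batch shift; per-feature sampling noise of batch means remains, which is
  why the tests assert the signed mean shift collapses rather than every
  feature's difference.
- **Intersection and standardization** keeps the cross-cohort feature
  intersection, stores each cohort's per-feature medians on the
  pre-standardization (size-normalized, batch-adjusted) scale, and z-scores
  within cohort. Dichotomization thresholds live on that stored scale; the
  published UMI-valued threshold of the headline marker suggests a
  count-scale value, and the batch-adjusted pre-standardization scale is the
  closest count-like scale available after correction.

## Survival statistics

Cox models use Breslow ties and tolerance 1e-9 throughout; inference is
Wald (the style in which hazard ratios with 95% CIs are conventionally
reported). Medians with even n are the mean of the central order
statistics; the high group of a dichotomization is `value >= threshold`,
matching the published "greater-or-equal" convention, and rules fitted on
discovery are applied unchanged to replication. The cutpoint optimizer
scans all observed values, maximizes |log HR|, breaks ties toward the
smaller threshold, and refuses splits leaving either arm under 10% of the
cohort — without the guard the optimum drifts to near-degenerate splits
with enormous, meaningless hazard ratios. AUC(t) is the IPCW
cumulative/dynamic estimator with Kaplan–Meier censoring weights evaluated
at the left limit; the default grid is the unique event times inside the
follow-up range and the summary is the unweighted mean over that grid.
When a log-rank comparison needs a median difference and one arm never
reaches S = 0.5, the difference is reported as undefined (NA) rather than
substituting a restricted median.

## Feature selection

`make_subsets()` draws subsets of 20 with a per-feature coverage guarantee
of 50. The sampler is deficit-driven: the focal feature is drawn among the
currently least-covered, companions are sampled at random preferring
features still short of coverage. This keeps the realized design near the
counting bound `n * coverage / size` (3,700 at the reference scale; the
sampler lands within a few subsets of it) while every membership remains a
random draw. Coverage conservation (sum of subset sizes = sum of coverages)
is a tested invariant.

`sfs_cv()` runs sequential forward selection from the empty set with
baseline concordance 0.5: each step adds the feature maximizing the mean
k-fold cross-validated C-index (folds stratified by event indicator so
every fold contains events, assigned once per subset and shared across all
candidate evaluations), stopping at the first non-improving addition; ties
break to the lowest feature index for determinism. Because the greedy path
is monotone under this stopping rule, the returned set is also the path
argmax. The returned score is the path maximum and therefore carries mild
selection optimism above 0.5 on null data — the tests bound it rather than
pretending it is exactly 0.5. A learner failing in one fold skips the fold
with a warning; a subset whose every fold fails is skipped.

Frequency selection keeps features selected in at least 90% of the subsets
containing them. The refinement round re-subsets the survivors under the
same coverage rule (a fixed subset count can be imposed instead), records
each subset's best C-index, and applies an elbow threshold per learner:
values are sorted descending, both axes normalized to [0, 1], and the
threshold is the value with maximum perpendicular distance to the chord —
invariant to affine rescaling. A straight ramp has no distinct elbow; the
implementation warns and returns the smallest value. With fewer than three
refinement subsets the elbow is skipped and all survivors are kept.
Features are retained when a subset that selected them beats the elbow
threshold, and the final panel is the union of the per-learner panels —
union semantics are one reading of a multi-learner "final panels" merge,
and the step is explicit in the report.

Learners satisfy a minimal contract (`fit`, `risk`; higher risk = earlier
predicted event; deterministic under a fixed seed). The native Cox learner
is sufficient for the whole procedure; random-survival-forest (ranger) and
gradient-boosted Cox (xgboost) adapters ship with the hyperparameter
presets used at reference scale, echoed verbatim in `preset_rsf()`,
`preset_xgb_selection()`, and `preset_xgb_tuned()`. Fields of those presets
that name concepts specific to other implementations (e.g.
`min_weight_fraction_leaf`) are carried in the preset for configuration
fidelity and mapped where the backing library has an equivalent.

## Explanation

Attributions are computed on the per-sample log-risk (linear predictor) —
the scale on which exponentiation yields hazard-ratio-like quantities. For
linear risk the exact interventional Shapley value is
`phi_ij = beta_j (x_ij - bg_j)` with the background `bg` = training feature
means; for arbitrary learners a permutation estimator averages marginal
contributions over sampled orderings with absent features held at the
background. Both satisfy efficiency exactly (the permutation estimator
telescopes within each ordering). The attribution-derived hazard ratio of
feature j divides the mean of `exp(phi_ij)` over patients strictly above
the feature mean by the mean over those at or below it; the strict-above
boundary is deliberate and a feature with an empty side reports NA. This
ratio is *not* invariant to shifting a patient's attributions by a
constant — it is a ratio of group means of exponentials, which the tests
document rather than hide.

## Problem sizes and numerical choices

The test suite exercises the reference-scale combinatorics exactly (the
1,480-feature subset design is cheap) and scales the simulation-backed
checks to desk size as a package choice: hazard-ratio recovery at n = 2000;
recovery of the planted marker by the ensemble at 100 features, subsets of
10, coverage 10, 5-fold CV, 50 replicates; oracle equivalences at 100–1000
random cases each; and the isomiR-versus-aggregate discrimination property
at 20 replicates of a scenario where the signal sits in a low-abundance
isomiR under an abundant null major form of the same gene. Master seeds
derive child seeds through a fixed linear map kept below 2^31. The
analysis scripts run at 120 features with the median imputer; the DAE
imputer is exercised at reduced layer sizes in the tests.

## Known limitations

The caller models end offsets plus substitutions, not internal indels; the
nomenclature reproduces the published exemplars but the supplementary
grammar it mirrors may define tokens (e.g. `.as`, `.T.A`) differently; the
DAE imputer is a contract-level implementation, not a reproduction of the
external imputation software's internals; ComBat-style adjustment assumes
batch effects independent of outcome; and the generator's independence
assumptions (clinical marginals, MCAR dropout) mean that passing tests
bound implementation correctness, not clinical validity on real cohorts.
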