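---
title: "Methods: longitudinal metabolomics module trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal metabolomics module trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metamodtrend` analyses small longitudinal untargeted-metabolomics cohorts:
tens of patients, at least three visits each over a few years, hundreds of
profiled metabolites, per-visit disability and quality-of-life scores. This
vignette is the package's own account of the statistical machinery, the
parameters that matter, and the choices made where the design was genuinely
open.

## Preprocessing

Untargeted profiling yields positive relative abundances with substantial
missingness, much of it left-censored at the detection limit. The pipeline
(`preprocess_pipeline()`):

1. **Missingness filter.** A metabolite is removed when its missing
   fraction is *strictly greater* than `missing_frac_max` (default 0.30):
   3 missing out of 10 samples survives a 30% cutoff, 4 does not.
2. **KNN imputation** (`knn_impute()`, `knn_k = 10`). Neighbours are
   metabolites, the usual omics convention (a sample axis is available via
   `impute_axis` for sensitivity checks). The distance between two
   metabolites is the root-mean-square difference over samples where both
   are observed — i.e. Euclidean distance normalized by the shared-sample
   count, so metabolites with different missingness patterns are
   comparable. Pairs with no shared samples are never neighbours. A
   missing entry becomes the unweighted mean of the k nearest metabolites
   observed in that sample; fewer than k available → those available; none
   → the metabolite's own observed median. Ties in distance break by
   metabolite id order, making imputation deterministic. Observed values
   are never modified, so imputation is idempotent.
3. **Normalization.** Each metabolite is divided by its own median across
   samples and natural-log transformed. The pre-log median is therefore
   exactly 1 for every metabolite, and the result is invariant to
   per-metabolite rescaling of the raw values. Imputation runs on raw
   abundances *before* scaling; the order is configurable in principle but
   fixed here because scaling after imputation keeps the median contract
   exact.

## Correlation network modules

`correlation_adjacency()` raises pairwise Pearson correlation across
samples to the soft power `soft_power` (β, default 12; unitless). The
default network is **unsigned** (`|r|^β`); a signed variant
(`((1+r)/2)^β`) is available when anticorrelated metabolites should not
share modules. `tom_similarity()` converts adjacency to topological
overlap, and `detect_modules()` clusters 1 − TOM by average linkage with a
**static cut** at `tree_cut_height`, keeping clusters of at least
`min_module_size` (default 10) as colour-labelled modules (canonical
size-ordered palette; "grey" = unassigned).

A static cut is a deliberate simplification of the dynamic hybrid tree
cut used by canonical weighted correlation network analysis: it is fully
deterministic and easy to reason about. Its height must respect the TOM
scale that β induces. At β = 12 a module with within-correlation ≈ 0.6
has TOM around 2×10⁻³, so within-module dissimilarities span roughly
0.997–0.9997, while uncorrelated features sit above 1 − 10⁻⁶. The default
`tree_cut_height = 0.9999` sits inside that wide separation band: on
synthetic cohorts it recovers planted modules essentially perfectly while
leaving independent features grey. Heights at 0.999 or below amputate the
weaker members of a ρ = 0.6 module; heights within 10⁻⁶ of 1 would start
absorbing noise. If you change β, revisit the cut height: lower β inflates
TOM and tolerates lower cuts.

`eigenmetabolites()` summarizes each module by the first principal
component of its standardized member profiles, scaled to unit sample
variance. PCA sign is arbitrary, so the score is oriented to correlate
non-negatively with the mean standardized member profile; a one-metabolite
module's eigen-metabolite is that standardized profile. `module_membership()`
reports kME — each metabolite's correlation with each eigen-metabolite —
sorted hub-first within module.

## Mixed-model trend testing

For each feature (metabolite or eigen-metabolite), `trend_scan()` fits

y_ij = β₀ + β₁·t_ij + γ′z_i + b_i + ε_ij,  b_i ~ N(0, σ²_b), ε ~ N(0, σ²_e)

with t in years from each patient's own baseline and covariates z (age at
baseline, sex, prior-DMT flag; sex is coded female = 1 and prior DMT = 1 —
the coding only flips coefficient signs). The model is random-intercept
only: it is the minimal model for repeated measures per patient, and with
~30 patients and ~4 visits random slopes are rarely identifiable. Fitting
is REML (via `lme4`); inference is the Wald normal approximation
(CI = β̂₁ ± 1.96·SE, p from N(0,1)). That approximation slightly
understates small-sample uncertainty relative to finite-df corrections;
the package therefore validates it by simulation — at the default design
(31 patients × 4 visits, β₁ = −0.10, σ_b = 0.3, σ_e = 0.2; 500
replicates) bias is below 0.01 and empirical 95% CI coverage lies in
[0.92, 0.98], and a within-patient time-permutation null over 200 features
keeps the 5% false-positive rate within [0.03, 0.07]. Rank-deficient
designs are rejected naming the collinear column; per-feature fit failures
become NA rows, never silent drops. FDR control is Benjamini–Hochberg
(`bh_adjust()`, delegating to `stats::p.adjust`), applied across
metabolites within the metabolite scan; exploratory clinical models are
reported unadjusted.

## Pathway enrichment

`rank_statistics()` orders metabolites by s_m = sign(β̂₁)·(−log₁₀ p)
(p floored at machine epsilon; ties break lexicographically by id). The
statistic must be signed — enrichment reports up- versus down-regulated
pathways — and this is the minimal signed transform of the trend scan's
p-values. `enrichment_score()` is the weighted Kolmogorov–Smirnov running
sum (hits add |s|^w normalized, default `gsea_weight = 1`; misses subtract
1/(N − n_set)); the ES is the signed maximum deviation, with an exact
positive/negative tie resolving to the positive side. `gsea_scan()` builds
the null by metabolite-label permutation — random same-size sets, one
shared null per set size — because the ranking comes from per-feature
models, so no sample-level phenotype permutation exists at this layer.
For each pathway, p = (1 + #{same-sign |ES*| ≥ |ES|}) / (1 + #same-sign)
(add-one corrected, so p > 0), and NES = ES / mean|ES*| over same-sign
permutations, which adjusts for pathway size. Defaults: `gsea_min_set = 5`,
`n_permutations = 1000`, granularity = sub-pathway. A seed is mandatory.

One caveat the synthetic tests make visible: the label-permutation null
assumes exchangeable metabolites. Strongly co-regulated pathways violate
that — a correlated module can drift coherently within a small cohort and
reach nominal significance without a planted trend. Calibration holds for
pathways of independent metabolites; treat enrichment of tight modules as
corroborating, not independent, evidence alongside the eigen-metabolite
mixed model.

## Disability and quality-of-life outcomes

`edss_plus_improved()` and `odrs()` implement the composite rules on each
patient's baseline versus **last available** visit. EDSS-Plus improvement:
EDSS decrease ≥ 1.0 from baseline ≤ 5.5, or ≥ 0.5 from baseline > 5.5, or
a ≥ 20% reduction in T25FW or either 9HPT time (all boundaries inclusive).
ODRS components: EDSS ±1 at the stratum threshold, each timed test ±1 at a
15% reduction/increase; total in [−4, +4], improved iff total > 0
(strict). The published composite defines EDSS improvement only; ODRS
needs a worsening rule, so the same stratum magnitudes are mirrored as
increases — a documented assumption, chosen as the literal reading of
"the same threshold" over the conventional 1.5/1.0/0.5 progression strata.
The implied containments hold by construction and are unit-tested: an
ODRS EDSS +1 or a ≥ 20% timed gain implies EDSS-Plus improvement, while a
15% timed gain scores ODRS +1 without reaching the 20% EDSS-Plus bar.

`wilcoxon_signed_rank()` drops zero differences, midranks ties, and
returns the exact two-sided p by full sign enumeration when the effective
n ≤ 15 with no ties (the enumeration is a rank convolution, identical to
brute force), otherwise the normal approximation with tie correction and a
0.5 continuity correction; all differences zero gives p = 1 with a
warning. `neuroqol_improvement()` calls a per-item improvement when the
change in the item's favourable direction *strictly* exceeds its minimal
detectable change. The shipped per-item MDC of 5 T-score points is a
synthetic placeholder (about half an SD on the T metric): validated
conditional MDCs are published externally and must be supplied through
`analysis_config(neuroqol_mdc = ...)` for real analyses.

## Metabolome–outcome association

`delta_features()` computes last-minus-baseline change per patient per
feature on the processed scale and z-standardizes across patients, so
logistic coefficients are per SD of change; zero-variance features are
flagged non-informative, and a single-patient input skips standardization
with a flag. `logistic_improvement()` fits improvement ~ delta + age +
sex + follow-up years + DMT by binomial IRLS (`stats::glm`, deviance
tolerance 1e-8, ≤ 100 iterations) and reports OR = exp(β̂) with a Wald 95%
CI. "Years of follow-up" is each patient's last visit time — total
follow-up. Complete separation (non-convergence, |β̂| > 15, or perfect
classification) is flagged and no OR reported; with ~30 patients
separation is common and rescuing it (e.g. by penalization) is explicitly
out of scope. `partial_spearman()` rank-transforms x, y, and covariates
(midranks), residualizes the ranked x and y on the ranked covariates by
least squares, and correlates the residuals, with p from the t
distribution on n − 2 − k df; residuals that are numerically null (an
input fully explained by covariates) return ρ = 0 rather than a ratio of
rounding noise.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code that defines the study
conditions, not a tuning dial. On the log scale, metabolite m of module M
in patient i at visit j is

x = μ_m + √ρ · f_{M,ij} + b_{mi} + δ_M · t_ij + ε,  ε ~ N(0, 1 − ρ),

with a shared standard-normal module factor f per sample, per-patient
intercepts b (SD 0.2), and per-year module slopes δ; abundances are
exp(x). Defaults: 31 patients; 4 visits at 0/1/2/3 years (baseline exactly
0; later visits jittered ±0.15 y, reflecting real ~15-month sampling
intervals); 300 metabolites with planted modules of 40/30/25/20 at nominal
within-module correlation ρ = 0.6 (the patient-intercept variance makes
the realized correlation ≈ ρ/1.04); modules 1 and 2 carry slopes −0.10 and
−0.12 log-units/year, mirroring a design with two treatment-altered
modules among ~12; age ~ N(41, 10), P(female) = 0.68, P(prior DMT) = 0.71;
missing rate 0.10 with half the masked entries drawn from each
metabolite's lowest quartile (left-censoring; the mechanism of real
missingness is unknown, so the censored share is an explicit assumption).
Improvement is Bernoulli with logit linear in the standardized change of
the target module's latent score at OR 0.3 per SD; the intercept is solved
numerically so the marginal prevalence is 0.29 (≈ 9 of 31 improved).
Clinical trajectories are then drawn consistent with each label: improved
patients cross the EDSS and timed-test improvement thresholds by
construction, others stay strictly inside every threshold; neuro-QOL
T-scores are N(50, 8) with a favourable drift of 2 T-points/year for
improved patients.

What the generator does **not** emulate: batch and instrument drift,
heavy-tailed or skewed abundance noise, missingness that depends on the
treatment effect, relapses or non-monotone disability trajectories, and
overlap between modules and pathways beyond the planted one-to-one map.
Passing tests therefore demonstrate correctness of the machinery and
calibration under a clean generative model — not robustness to every
artefact of real data.

## Numerical choices and degenerate inputs

- Determinism: every stochastic stage requires a seed; same seed + config
  reproduce all tables byte-for-byte (`write_results()` writes with fixed
  separators and full precision).
- EDSS values off the 0–10 half-point grid are rejected at load with the
  offending row; duplicated ids, orphan samples, and non-positive
  abundances or times are rejected before any analysis runs.
- TOM denominators ≤ 0 (unreachable for valid adjacency) would emit 1;
  adjacency entries are clipped to [0, 1] against floating-point overshoot.
- Zero-variance metabolites are rejected by id before correlation;
  all-grey partitions are an error for eigen-metabolite extraction and a
  warning (not an error) for module detection.
- The REML fit falls back to a floored-variance GLS standard-error formula
  when the variance–covariance matrix is degenerate (noise-free inputs).
- Validation problem sizes were chosen to exercise each property at
  adequate power while keeping the default suite a few minutes long: 20
  cohorts for module recovery, 500 replicates for mixed-model calibration,
  200 features for the permutation null, 200 seeds × 20 pathways for
  enrichment size, 500 random vectors for the signed-rank oracle, 51
  replicates of n = 500 for odds-ratio recovery.

## Known limitations

Single-arm trends conflate treatment with time; the pipeline quantifies
change, not causation. Wald inference is approximate at very small n.
The static tree cut trades the adaptivity of dynamic cutting for
determinism and must be kept consistent with β. The enrichment null
assumes metabolite exchangeability (see above). Separation-prone logistic
fits are flagged, not rescued. MSFC composite z-scores and
processing-speed norming are out of scope.
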