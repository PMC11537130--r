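# metamodtrend

Longitudinal untargeted metabolomics asks whether a treatment reshapes the
circulating metabolome over follow-up, and whether that reshaping tracks
clinical change. `metamodtrend` implements that analysis as a tested,
reusable R pipeline for small repeated-measures cohorts (tens of patients,
a few visits each over several years, hundreds to ~1000 profiled
metabolites), the setting typical of single-arm treatment studies in
relapsing–remitting multiple sclerosis and similar diseases. It is aimed at
biostatisticians and computational biologists who have a metabolite
abundance table, per-visit clinical scores, and patient covariates, and
want module-level trend and response results rather than one-off scripts.

## What it computes

**Preprocessing.** Metabolites missing in more than 30% of samples are
removed; remaining gaps are imputed by K-nearest-neighbour imputation over
metabolites (k = 10; distance = RMS difference over shared observed
samples); values are median-scaled per metabolite and natural-log
transformed.

**Correlated-metabolite modules.** A weighted correlation network with
soft-threshold power β = 12, *a<sub>ij</sub>* = |*r<sub>ij</sub>*|<sup>β</sup>,
is converted to topological overlap

> TOM<sub>ij</sub> = (l<sub>ij</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>),  l<sub>ij</sub> = Σ<sub>u≠i,j</sub> a<sub>iu</sub>a<sub>uj</sub>,

clustered by average linkage on 1 − TOM with a static cut, and
colour-labelled by decreasing size (turquoise, blue, brown, ...). Each
module is summarized by its **eigen-metabolite** — the first principal
component of the standardized member profiles — and each metabolite by its
module membership kME (correlation with the eigen-metabolite).

**Trend testing.** Per metabolite and per eigen-metabolite, a
random-intercept linear mixed model
*y<sub>ij</sub>* = β₀ + β₁·t<sub>ij</sub> + γ′z<sub>i</sub> + b<sub>i</sub> + ε<sub>ij</sub>
with time in years from each patient's own baseline, adjusted for age at
baseline, sex, and prior disease-modifying-therapy (DMT) history, fitted by
REML with Wald inference and Benjamini–Hochberg FDR across metabolites.

**Pathway enrichment.** Metabolites ranked by sign(β̂₁)·(−log₁₀ p) feed a
weighted GSEA running sum; pathways (≥5 members) get a permutation
normalized enrichment score NES = ES / mean|ES*| and BH-adjusted
permutation p-values.

**Disability response.** EDSS-Plus improvement (≥1.0-point EDSS decrease
from baseline ≤5.5, ≥0.5 from baseline >5.5, or ≥20% faster T25FW/9HPT)
and the Overall Disability Response Score (ODRS: four ±1/0 components, 15%
timed-test thresholds, total in [−4, +4], improved iff total > 0), plus a
Wilcoxon signed-rank test for EDSS change and per-item neuro-QOL
improvement against minimal-detectable-change thresholds.

**Association.** Logistic models of improvement on each feature's
standardized change (OR per SD, adjusted for age, sex, follow-up years,
DMT), and partial Spearman correlations between module changes and
neuro-QOL changes.

Because studies of this design rarely deposit patient-level data, the
package ships a first-class synthetic cohort generator
(`generate_cohort()`) with planted correlated modules, treatment trends,
left-censored missingness, and an improvement outcome linked to one
module — with full ground truth, so every stage is testable end to end.

## Worked example

```r
library(metamodtrend)
d   <- generate_cohort(sim_config(seed = 1))   # 31 patients x 4 visits, 300 metabolites
res <- run_pipeline(d, analysis_config(seed = 1))

table(res$modules)
#>      blue     brown      grey turquoise    yellow
#>        30        25       186        39        20

res$trend_modules
#>     feature estimate ci_low ci_high      p     q
#> 1      blue  -0.1435 -0.296 0.00933 0.0657 0.263
#> 2 turquoise  -0.1103 -0.268 0.04718 0.1698 0.340
#> 3    yellow   0.0896 -0.066 0.24508 0.2591 0.345
#> 4     brown  -0.0408 -0.200 0.11860 0.6158 0.616

head(res$enrichment, 4)
#>                 pathway size     es   nes       p  p_adj direction
#> 1     planted_pathway_4   20  0.768  2.58 0.00398 0.0305        up
#> 2     planted_pathway_2   30 -0.717 -2.09 0.00123 0.0142      down
#> 3 background_pathway_25   10  0.754  2.05 0.00643 0.0370        up
#> 4     planted_pathway_1   40 -0.636 -1.96 0.00118 0.0142      down

table(res$disability$odrs_improved)
#> FALSE  TRUE
#>    22     9
```

The four planted modules are recovered almost exactly (one weak member
stays grey at this seed); the two planted trend modules (turquoise and
blue, simulated slopes −0.10 and −0.12 log-units/year) carry the most
negative eigen-metabolite slopes, their pathways are the top down-regulated
enrichments, and 9 of 31 simulated patients are ODRS-improved. Eigen-
metabolite slopes are in unit-variance score units per year, so they match
the simulated member slopes in sign and order, not numerically.
`write_results(pipeline_tables(res), "out/")` writes every table as TSV
plus a run manifest; identical inputs and seed reproduce the files
byte-for-byte.

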