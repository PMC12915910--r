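# mstriad

Outcome-agnostic taxonomic screening of clinical variables via
Marczewski–Steinhaus triad distances.

## What problem this solves

Risk-factor panels in conditions like acute pulmonary embolism (APE) are
redundant: univariate Cox and logistic regressions flag a dozen-plus
"significant" predictors, led by non-modifiable background traits such as
age, and say little about which biomarkers are actively shaped by the
disease. `mstriad` implements a structural, outcome-agnostic complement
for biostatisticians and clinical epidemiologists: it ranks variables by
their contribution to inter-patient heterogeneity, never looking at the
endpoint.

## The method in brief

For non-negative measurements the Marczewski–Steinhaus dissimilarity
between patients A and B is the scale-free ratio

    D = |A − B| / max(A, B)  ∈ [0, 1].

The pipeline:

1. enumerates all C(p, 3) variable **triads** (1,140 for a 20-variable
   panel; each variable present in 171, absent from 969);
2. computes each triad's mean M–S distance over all C(n, 2) patient
   pairs and ranks triads ascending — the **scree series**;
3. fits a continuous two-segment **broken-stick regression**
   `y = a + b₁x + (b₂ − b₁)(x − ψ)₊`, with the change-point ψ profiled
   exhaustively over integer ranks and refined by golden-section search,
   separating the homogeneous from the heterogeneous triad regime;
4. tests each variable's presence across the two segments with an
   uncorrected Pearson chi-square, `N(ad − bc)²/(r₁r₂c₁c₂)`, classifying
   it as **pattern 1** (random), **pattern 2** (low-variability-segment
   predominant, a stable background trait) or **pattern 3**
   (high-variability-segment overrepresented, a disease-active signal);
5. benchmarks against the classical outcome-dependent view:
   Kaplan–Meier curve, Harrell's C on univariate Cox linear predictors,
   and AIC = 2k − 2 ln L from univariate logistic fits.

Because the original hospital cohort is not deposited, the package ships
(a) the published per-variable descriptive statistics and segment counts
as reference tables (`ape_panel_reference()`, `ape_segment_counts()`)
and (b) a moment-matched synthetic cohort generator
(`default_cohort_spec()`, `generate_cohort()`) emulating the 366-patient,
20-variable panel with 76 one-year deaths, so every stage is testable.

## Worked example

```r
library(mstriad)

spec <- default_cohort_spec(planted = c("CRP", "hsTnT", "D-dimer", "CK-MB mass"),
                            coupling = 2)
cohort <- generate_cohort(spec, seed = 1)   # 366 x 20, 76 events
scree  <- scan_triads(cohort)               # 1,140 ranked triads
fit    <- fit_segmented(scree)
fit
#> <segmented_fit> n = 1140
#>   change-point  1035.68
#>   slope1        0.0002915 (p = <2e-16)
#>   slope2        0.001058 (p = <2e-16)
#>   slope ratio   3.629
#>   RSS 0.186874 (single line 0.355657)

classify_patterns(segment_enrichment(scree, fit))
#> Pattern 1 (random, no segment differentiation):
#>   CREA, GLU, INR, WBC, PLT, UREA, GFR, aPTT
#> Pattern 2 (low-variability segment predominant):
#>   Cl-, K+, Na+, Hb, RBC, Age, BMI
#> Pattern 3 (high-variability segment overrepresented):
#>   aD-dimer, hsTnT, CK-MB mass, CRP, D-dimer
```

Reading: past the change-point, mean structural divergence grows ~3.6×
faster per rank; the four planted disease-active markers (plus aD-dimer,
whose published coefficient of variation is the panel's highest) dominate
the heterogeneous segment, while electrolytes, haemoglobin and age act as
stabilising background traits.

The same enrichment stage applied to the published segment counts
reproduces the printed statistics:

```r
head(enrich_counts(ape_segment_counts())[, c("variable", "chi2", "pattern")], 3)
#>   variable  chi2 pattern
#> 1 CRP       62.3       3
#> 2 D-dimer   55.2       3
#> 3 hsTnT     39.5       3
```

`run_pipeline(pipeline_config(...))` orchestrates all stages and writes
each artefact (descriptives, scree CSV, segmented-fit JSON, enrichment
CSV, Kaplan–Meier CSV, extreme-triad Newick dendrograms, markdown report,
manifest with seed and config fingerprint) to an output directory.

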