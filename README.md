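# mtapet

Metabolic tumour burden quantification on FDG-PET and its prognostic
modelling for lymphoma, in R.

In diffuse large B-cell lymphoma (DLBCL), baseline FDG-PET tumour burden
predicts outcome under first-line R-CHOP. The established burden metric,
total metabolic tumour volume (TMTV), requires contouring every lesion;
the **metabolic tumour area (MTA)** — the maximum axial cross-sectional
area of the largest lesion — is a fast single-slice surrogate with
comparable prognostic value, particularly for splitting the high-risk
NCCN-IPI ≥ 4 group into subgroups with distinct outcomes. This package
implements the whole pipeline:

* **Imaging / SUV** — NIfTI volume and organ-mask I/O, body-weight SUV
  conversion (SUV = C·W/D).
* **Segmentation** — percentage-of-maximum lesion delineation: hill-climb
  to the lesion's local peak, threshold at 41% of the peak SUV,
  26-connected region growing, with physiologic-uptake exclusion and
  focal/diffuse organ-inclusion rules (spleen involved on focal uptake or
  diffuse uptake > 150% of the liver mean).
* **Metrics** — TMTV (cm³), MTA (cm²), SUVmax and pooled SUVmean (g/ml)
  per patient, with the largest lesion chosen by metabolic volume:
  MTA = max over axial slices of (voxel count × dx·dy)/100 on that lesion.
* **Biostatistics** — ROC with Youden-index cut-off selection
  (J = sens + spec − 1, smallest cut-off on ties), Pearson correlation,
  variance inflation factors, ICC(2,1).
* **Survival** — Kaplan-Meier product-limit estimation, two-group log-rank
  test, and Cox proportional-hazards regression (Breslow/Efron ties,
  Newton-Raphson, Wald CIs), implemented from first principles and
  cross-checked against independent oracles in the test suite.
* **Prognosis** — NCCN-IPI scoring (0–8 points; groups 0–1/2–3/4–5/6–8;
  binary split at ≥ 4), biomarker dichotomization, and a staged analysis
  plan (cut-offs → univariate Cox → multivariate Cox → bivariate
  MTA + NCCN-IPI → stratified Kaplan-Meier with 3-year rates).
* **Synthetic data** — digital PET phantoms with analytic ground truth
  (Gaussian PSF, additive noise) and simulated survival cohorts with
  Weibull proportional-hazards structure and a realistic DLBCL covariate
  mix, used throughout the tests.

## Worked example

Two hot spheres on a cold background, segmented automatically and
summarised:

```r
library(mtapet)

ph <- make_phantom(phantom_spec(
  shape = c(48, 32, 32), spacing = c(2, 2, 2), background = 0.2,
  lesions = list(list(center = c(12, 16, 16), radius_mm = 15, peak = 12),
                 list(center = c(36, 16, 16), radius_mm = 6, peak = 7))))
lesions <- segment_all(ph$volume)
metabolic_profile(lesions)
#> Metabolic profile (2 lesions):
#>   TMTV      15.31 cm^3
#>   MTA        7.08 cm^2 (lesion 1, slice 15)
#>   SUVmax    12.00 g/ml
#>   SUVmean   11.68 g/ml
```

The 15 mm sphere digitises to 14.33 cm³ (analytic 14.14 cm³) and its
great-circle slice to 7.08 cm² (analytic π·1.5² = 7.07 cm²); the second
sphere adds ~1 cm³ to the TMTV but, being smaller, never contributes to
the MTA.

A simulated 280-patient cohort pushed through the staged analysis plan:

```r
coh <- simulate_cohort(cohort_spec(n = 280, seed = 1))
run_analysis_plan(coh, plan_config(endpoints = "pfs", metrics = "mta"))
#> == Endpoint: PFS ==
#> ROC / Youden cut-offs:
#>  parameter   auc   cutoff sensitivity specificity
#>        mta 0.618 1.319624       0.805       0.424
#> Univariate Cox:
#>        parameter    hr ci_lower ci_upper       p
#>              mta 2.113    1.481    3.016 <0.0001
#>     lugano_stage 1.168    0.864    1.579   0.313
#>  ...
#> Bivariate MTA + NCCN-IPI:
#>  parameter    hr ci_lower ci_upper       p
#>        mta 2.250    1.574    3.216 <0.0001
#>   nccn_ipi 2.217    1.652    2.976 <0.0001
#> Kaplan-Meier 3-year rates (%):
#>            stratification group   n events rate_3yr
#>                       MTA   low  74     38     79.7
#>                       MTA  high 206    157     52.9
#>  ...
#>  MTA within NCCN-IPI >= 4   low  35     21     85.7
#>  MTA within NCCN-IPI >= 4  high 111    101     42.3
```

High MTA carries a hazard ratio above 2 both alone and alongside the
NCCN-IPI, and splits the NCCN-IPI ≥ 4 subgroup into strata with 3-year
progression-free survival of 86% vs 42% — the reclassification behaviour
the MTA metric is designed to expose. The full report object also carries
the log-rank table and a run log of every cut-off and skip decision.

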