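---
title: "Quantifying metabolic tumour burden on FDG-PET and modelling its prognostic value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic tumour burden on FDG-PET and modelling its prognostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtapet)
```

## The problem

In diffuse large B-cell lymphoma (DLBCL), pre-treatment tumour burden on
FDG-PET predicts outcome under R-CHOP chemoimmunotherapy. The total
metabolic tumour volume (TMTV) is the established burden metric but is slow
to measure when disease is multifocal. The *metabolic tumour area* (MTA) —
the maximum axial cross-sectional area of the single largest lesion — is a
quick surrogate that can be read off a single transaxial slice. This
package implements the full quantification-and-prognosis pipeline around
these metrics: SUV imaging, percentage-of-maximum lesion segmentation,
metric extraction, cut-off selection, survival modelling, and NCCN-IPI risk
stratification, together with synthetic phantoms and cohorts that give
every stage a known ground truth.

## SUV model

Voxel values are body-weight standardized uptake values,
$\mathrm{SUV} = C \cdot W / D$ with $C$ the activity concentration in
kBq/ml, $W$ the body weight in grams and $D$ the injected dose in kBq
(`suv_convert()`). No lean-body-mass variant is offered and decay
correction is assumed to have been applied by the scanner, which is how
clinical SUV exports normally arrive. Axial slices are the $(x, y)$ planes
of the NIfTI grid; all geometry is voxel-grid plus spacing, so world
affines beyond voxel size are ignored.

## Lesion segmentation

`segment_lesion()` implements percentage-of-maximum thresholding: from a
seed voxel it climbs by steepest ascent over 26-neighbours to the lesion's
local peak, sets the boundary at a fraction (default 0.41) of that peak,
and keeps the 26-connected component of the supra-threshold region that
contains the peak, minus physiologic-uptake organs (brain, bladder,
kidneys, myocardium). Design choices worth stating:

* **Per-lesion reference maximum.** The 41% threshold is taken relative to
  each lesion's own peak, the behaviour of EANM-style clinical tools. A
  `threshold_mode = "patient"` option thresholds against the global SUVmax
  instead, and `"absolute"` gives fixed-SUV segmentation for sensitivity
  checks; the per-lesion default is the primary, tested path.
* **26-connectivity** is the most permissive standard 3-D connectivity and
  reproduces the "contour around the target lesion" behaviour of clinical
  workstations.
* **Determinism.** Plateaus in the hill climb and ties in seed placement
  resolve to the lexicographically smallest voxel index, so identical
  inputs always give identical lesions, and any seed within a lesion's
  basin of attraction yields the same contour (tested property).
* **Automatic seeding.** `auto_seeds()` places one seed per 26-connected
  component of {SUV ≥ 2.5} — SUV 2.5 being a conventional
  lesion-detection floor — at the component's hottest voxel. Manually
  supplied seeds always take precedence in `segment_all()`, mirroring the
  physician-click workflow the automatic mode replaces.
* **Organ rules.** The spleen counts as involved on focal uptake or on
  diffuse uptake exceeding 150% of the liver mean (strict inequality; a
  spleen at exactly 1.5× liver is not involved). When both rules fire the
  involvement is reported as diffuse: a uniformly hot spleen contains
  supra-threshold voxels too, but its uptake pattern is diffuse. Liver and
  bone-marrow lesions are retained only under focal uptake, for which the
  detection floor serves as the quantitative proxy of the (visual,
  unquantified) clinical call.

## Metabolic metrics

For a lesion set on a grid with spacing $(d_x, d_y, d_z)$ mm:

* $\mathrm{TMTV} = \sum_\ell |\ell| \, d_x d_y d_z / 1000$ cm³;
* MTA = the maximum over axial slices of (in-slice voxel count ×
  $d_x d_y / 100$) cm², evaluated on the *largest* lesion only;
* SUVmax = hottest voxel over all lesions; SUVmean = pooled mean over all
  lesion voxels.

"Largest" means largest metabolic volume (ties: higher peak SUV, then
lower id) — the natural reading in a TMTV context; a slice of another
lesion crossing the same plane never contributes to the MTA. The pooled
SUVmean weights lesions by size; an unweighted mean of per-lesion means is
available via `mean_mode = "per_lesion"`. MTA is an error, not zero, for an
empty lesion set: an empty set means nothing was measured, not that the
area was measured to be nought.

## Synthetic data: what it does and does not emulate

`make_phantom()` builds PET volumes from uniform spheres or Gaussian foci
on a uniform background, optional box/ellipsoid organ compartments, an
isotropic Gaussian point-spread function parameterised by FWHM (6 mm is
typical clinical PET) and additive Gaussian noise on SUV. The ground-truth
record carries each lesion's analytic 41%-isocontour volume and maximal
axial area — for a Gaussian focus the isocontour radius is
$\sigma\sqrt{2\ln(1/0.41)}$ — so segmentation and metrics can be checked
against closed forms. The phantoms deliberately do *not* model anatomy,
Poisson sinogram noise or reconstruction artefacts; passing phantom tests
shows the geometry and arithmetic are right, not that segmentation is
robust to clinical image quality.

`simulate_cohort()` draws clinical covariates matching a realistic
first-line DLBCL mix (age bands 7.5/24.3/47.9/20.4%, elevated LDH 45.4%,
advanced Ann Arbor stage 58.9%, ECOG ≥ 2 30.4%, multi-site extranodal
disease 40.7%, 51.8% male) and an MTA from a log-normal with median
2.37 cm²; the log-scale SD of 1.23 is the average of the two values implied
by quartiles 0.95 and 5.02 cm². The elevated-LDH mass is split 85/15
between the >1–3× and >3× bands, a split baseline tables rarely report.
Event times follow a Weibull proportional-hazards model
$S(t\mid x) = \exp\{-(t/\lambda)^{k} e^{\beta^\top x}\}$ with
administrative censoring; the default shape $k = 1$ makes the baseline
exponential so Kaplan-Meier curves have closed forms in tests. Default
true effects act on dichotomised MTA (cut-offs 1.36/5.73 cm² for PFS/OS)
and the NCCN-IPI ≥ 4 indicator with log-hazard-ratios ln 2.617/ln 2.633
(PFS) and ln 2.021/ln 3.869 (OS); baseline scales of 280 and 380 months
put the marginal 3-year PFS and OS near 63% and 76%. Because the score
components are drawn independently, the *joint* NCCN-IPI score
distribution is narrower than in real cohorts even though every component
marginal matches; tests therefore only assert component marginals.

## Statistics

`roc_youden()` computes the AUC by the midrank (Mann-Whitney) statistic
and scans every observed marker value as a cut-off with the fixed
orientation "marker ≥ cut-off = high risk", maximising
$J = \mathrm{sens} + \mathrm{spec} - 1$; ties, including float-level ones,
resolve to the smallest cut-off so reported cut-offs are data-supported
and reproducible. `vif()` is $1/(1-R^2)$ from ordinary least squares with
exact collinearity mapped to `Inf`. `icc_agreement()` is ICC(2,1) —
two-way random effects, absolute agreement, single measures — chosen
because inter-observer agreement of a measurement procedure should be
penalised for systematic offsets; this variant choice is an assumption, as
agreement studies often leave the model unstated.

Survival machinery is implemented from first principles and cross-checked
in tests against the independent `survival` package: the product-limit
estimator (`km_estimate()`, right-continuous step evaluation via
`survival_at()`; "3-year rate" = the curve at 36 months), the two-group
log-rank test with hypergeometric variance, and Cox regression
(`cox_fit()`) maximising the Breslow partial likelihood (Efron optional)
by Newton-Raphson with step-halving. Convergence requires the largest
score component below 1e-8 or a log-likelihood change below 1e-10 within
100 iterations; confidence intervals are Wald, matching how hazard ratios
are reported in clinical tables. Monotone likelihoods (complete
separation) are flagged as non-convergence rather than returned as huge
estimates. Records with time 0 are kept and are at risk only
instantaneously.

## NCCN-IPI and the analysis plan

`nccn_ipi()` scores age (0/1/2/3 points at ≤40, 41–60, 61–75, >75 —
band edges following the ≤60/≤75 table convention), LDH ratio (0/1/2 at
≤1, >1–≤3, >3), Ann Arbor III/IV (1), ECOG ≥ 2 (1) and major-organ
extranodal involvement (1). Stage and performance status are scored as two
separate components — the only reading consistent with the documented
0–8 maximum. Risk groups 0–1 / 2–3 / 4–5 / 6–8 partition the range, and
the binary ≥ 4 split agrees with group membership by construction (tested
on 10⁴ random records).

`run_analysis_plan()` chains the stages the way a prognostic-marker study
is analysed: ROC/Youden cut-offs per metric and endpoint (cut-offs may
instead be supplied, e.g. from a reference publication; both modes are
logged), univariate Cox for each metabolic and clinical parameter,
a multivariate model over the univariately significant ones (entry
criterion p < 0.05, configurable), a bivariate model of dichotomised MTA
plus the NCCN-IPI split, and Kaplan-Meier/log-rank comparisons including
MTA within the NCCN-IPI ≥ 4 subgroup. Strata without events are skipped
with an explicit run-log notice, never silently. One methodological note
the package's own simulations make visible: dichotomising a *null* marker
at its cohort-optimised Youden cut-off inflates the univariate rejection
rate well above the nominal 5% (cut-point dredging); the
`metric_form = "continuous"` mode avoids this, and the design-recovery
tests use it for exactly that reason.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based everywhere, including seed CSV/JSON files.
* All tie-breaks (hill-climb plateaus, seed ordering, largest-lesion and
  Youden ties) are lexicographic/smallest-first and documented, so every
  pipeline stage is deterministic given its inputs.
* Empty lesion sets: TMTV is 0, but MTA and SUV statistics raise errors.
* Degenerate statistical inputs (single-class ROC, zero-variance
  correlation, constant or collinear Cox covariates, zero-event log-rank)
  raise informative errors rather than returning NaN.
* Phantom and cohort generators restore the caller's RNG state, so
  embedding them in larger simulations does not perturb outer seeds.

## Validation scale

The shipped validation uses phantom grids of 32³–64³ voxels at 2 mm
spacing, 500 simulated null cohorts of n = 200 for type-I calibration,
200 cohorts of n = 500 for confidence-interval coverage, and 200 random
ROC datasets of n ≤ 50 for the exhaustive-search property — sizes at
which every oracle (closed-form geometry, scalar flood-fill, brute-force
likelihood search) is itself exactly computable.

## Known limitations

Segmentation assumes lesions are hotter than their immediate surroundings;
necrotic lesions with cold cores keep only their rim above threshold, so
MTA and TMTV describe viable-appearing tumour, not gross anatomical
extent. No partial-volume correction is applied. The organ
"focal uptake" proxy (peak ≥ detection floor) is a stated stand-in for a
visual clinical judgement. Cohort simulation draws NCCN-IPI components
independently and uses administrative censoring only; it is a testbed for
the statistical machinery, not a generative model of any real cohort.
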