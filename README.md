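# lesiondiff

Quantitative diffusion-MRI characterization and data-driven typing of
multiple sclerosis (MS) white-matter lesions.

MS plaques differ widely in how much demyelination and axonal damage they
carry, and conventional MRI barely sees that difference. `lesiondiff` is an R
package for analysts who want to (1) turn multi-shell diffusion MRI into
per-lesion tissue metrics, (2) split lesions into two severity types with
honest replication evidence, and (3) test whether a patient's burden of the
damaged type predicts disability — all with permutation inference, and all
testable end to end on synthetic cohorts with known ground truth.

## What it computes

**Diffusion metrics.** Macroscopic tensor metrics by log-linear least squares
on the low shell — FA, MD, RD, AD with the exact identity
MD = (AD + 2 RD)/3 — and microscopic spherical-mean metrics from all shells.
The powder average of an axially symmetric micro-tensor,

    eps(b) = exp(-b l_perp) * sqrt(pi) * erf(sqrt(b (l_par - l_perp))) / (2 sqrt(b (l_par - l_perp))),

yields uAD, uRD, uMD, uFA (`fit_smt()`); the two-compartment stick +
tortuosity-zeppelin model,

    eps(b) = f_in * eps_stick(b; l) + (1 - f_in) * eps_zeppelin(b; l, (1 - f_in) l),

yields the intra-neurite volume fraction f_in, intrinsic diffusivity
lambda_diff, and the extra-neurite diffusivities v_AD = (1 - f_in) lambda_diff
and v_MD = (lambda_diff + 2 v_AD)/3 (`fit_mcsmt()`). Noise-free round trips
recover truth to 1e-6 relative error; Rician bias correction is built in.

**Topography.** Connected components (26-connectivity), rule-based location —
periventricular (> 5% ventricle contact), juxtacortical (> 20% cortex),
infratentorial (> 50% brainstem + cerebellum), else deep white matter, in
that order — and a 27 mm³ minimum-volume filter (`label_components()`,
`classify_location()`, `summarize_lesions()`).

**Lesion typing.** Z-scored k-means with k = 2 (`kmeans2()`); the B type is
the centroid with lower f_in (more damage: lower FA, uFA, f_in; higher RD).
Stability is quantified by averaged prediction strength over 500 random
half-splits (`prediction_strength()`), with a column-shuffle permutation null
(`ps_null_pvalue()`), ceiling/variation screening of metrics
(`screen_metrics()`), feature-set search (`select_feature_sets()`) and
per-patient burden summaries (`patient_burden()`).

**Clinical statistics.** Freedman–Lane permutation tests for linear models
(`freedman_lane_lm()`), predictor-residual permutation for logistic models
(`perm_logistic()`), two-group permutation contrasts with bootstrap CIs
(`perm_group_diff()`), and Bonferroni control with an explicit family size
(`adjust_bonferroni()`).

**Synthetic data.** `gen_cohort()` simulates a 59-patient reference cohort
(per-location lesion rates, a latent 52:48 A/B mixture whose pooled moments
match published lesion statistics, clinical outcomes driven by true B-type
burden); `gen_dwi_voxels()` simulates multi-shell signals with Rician noise;
`gen_phantom_masks()` builds 3D label volumes with analytically known
topography. `run_pipeline()` chains everything from one validated config.

## Worked example

```r
library(lesiondiff)

# 1,000 synthetic lesions with a latent two-type mixture (52% B)
les <- simulate_lesion_features(1000, seed = 42)

model <- kmeans2(les, features = c("fa", "rd", "ufa", "f_in"), seed = 1)
tidy(model)
#> # A tibble: 8 x 4
#>   type  feature  value value_raw
#> 1 B     fa      -0.625     0.244
#> 2 B     rd       0.766     0.552
#> 3 B     ufa     -0.609     0.769
#> 4 B     f_in    -0.707     0.238
#> 5 A     fa       0.754     0.397
#> 6 A     rd      -0.925     0.384
#> 7 A     ufa      0.735     0.890
#> 8 A     f_in    0.854      0.446

prediction_strength(les, features = c("fa", "rd", "ufa", "f_in"),
                    n_splits = 500, seed = 1)
#> Mean prediction strength 0.999 over 500 random half-splits (k = 2, n = 1000)
```

The B centroid sits at lower FA (0.244 vs 0.397), lower microscopic FA
(0.769 vs 0.890), lower intra-neurite fraction (0.238 vs 0.446) and higher RD
(0.552 vs 0.384 ×10⁻³ mm²/s) — the more-damaged tissue profile — and the
two-cluster solution replicates across random halves far above the 0.8
threshold that marks a trustworthy clustering. The column-shuffle null
confirms the structure is not an artefact of the marginals:

```r
ps_null_pvalue(les[1:300, ], features = c("fa", "rd", "ufa", "f_in"),
               n_perms = 99, seed = 1)
#> Prediction strength 0.991 vs column-shuffled null (n_perms = 99): p = 0.01
```

`assign_types()` then types every lesion, `patient_burden()` aggregates per
patient, and `freedman_lane_lm()` / `perm_logistic()` relate B-type burden to
outcomes. `run_pipeline(analysis_config(...))` runs the whole chain and
writes TSV/JSON outputs plus the resolved configuration.

## Notes

- Diffusivities are reported in ×10⁻³ mm²/s throughout; FA, uFA and f_in are
  unitless.
- See `vignettes/lesion-typing-methods.Rmd` for the models, the design
  decisions (label conventions, permutation-null construction, thresholds)
  and the limits of what the synthetic validation shows.
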