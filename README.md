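# wmhnet

Lesion network damage from white matter hyperintensities: regional
disconnectome scoring, periventricular/deep lesion partitioning, and
ordinal outcome modeling — with a fully synthetic, seeded test world.

## What it does, and for whom

White matter hyperintensities (WMH) mark cerebral small vessel disease.
Their clinical impact depends not only on lesion volume but on *which*
white-matter connections they interrupt. For researchers studying stroke
outcome (or any setting where a binary lesion mask meets a reference
tractogram), `wmhnet` provides:

* **ChaCo scoring** — per atlas region $r$, the fraction of reference
  streamlines touching $r$ that pass through the lesion mask:

  $$\mathrm{ChaCo}(r) = \frac{\#\{s \in S_r : s \cap M \neq \emptyset\}}{\#S_r},
    \qquad S_r = \{s : r \in \mathrm{ends}(s)\},$$

  cleaned with the published rule (values `< 0.02` → 0, `> 1` → 1).
* **pWMH / dWMH partition** — WMH voxels within 10 mm (inclusive) of the
  ventricles are periventricular, the rest deep; exact anisotropy-aware
  Euclidean distance transform.
* **Group statistics** — one-sided one-sample t-tests per region against
  0; exclusion of near-degenerate regions (|skewness| > 1.3 or median
  exactly 0/1); paired mask-type comparisons by region or patient.
* **Outcome models** — per region, median-split high/low disconnectivity
  entered into a proportional-odds model for the ordinal mRS with
  residualized age and log10 WMH volume, NIHSS and log10 lesion volume as
  covariates; OR with 95% CI, Wald p, Nagelkerke R² gain over the base
  model, Benjamini–Hochberg FDR per mask type. The fitter is an in-package
  cumulative-logit MLE (validated against `MASS::polr` and, for binary
  outcomes, `glm`).
* **Synthetic data** — seeded toy atlas, ventricles, streamline connectome,
  per-patient WMH/stroke masks and proportional-odds outcomes emulating a
  33-patient severe-stroke cohort (age 70.7 ± 12.2, NIHSS 7.8 ± 3.6, WMH
  15.3 ml = 9.5 pv + 5.8 deep, stroke 37.9 ml), so everything above runs
  and is testable with no external data.

File formats: NIfTI-1 volumes (`.nii`/`.nii.gz`, built-in reader/writer),
TCK or a plain-text streamline dialect, CSV tables, JSON manifests.

## Worked example

```r
library(wmhnet)

cfg <- simulation_config(grid_shape = 24, voxel_size_mm = 3, n_regions = 8,
                         n_streamlines = 300, n_patients = 33,
                         causal_region_ids = c(1L, 2L), beta_disconnect = 2,
                         seed = 7)
cohort <- simulate_cohort(cfg)
head(cohort$cohort, 3)
#>   patient_id  age nihss mrs lesion_volume_ml wmh_volume_ml pwmh_volume_ml dwmh_volume_ml
#> 1       p001 73.4    10   2             42.3          13.4           7.64           5.72
#> 2       p002 81.8    12   3             41.8          12.6           7.42           5.16
#> 3       p003 51.2     9   0             22.8          16.1          11.74           4.35

m  <- cohort$chaco$cleaned$pwmh          # 33 patients x 8 regions
region_disconnection_test(m)[1:2, ]
#>   region_id  n  mean    t        p status
#> 1         1 33 0.573 33.4 9.09e-27     ok
#> 2         2 33 0.372 20.0 5.70e-20     ok

fr <- filter_regions(m)                  # skewness / median exclusions
fr$region_id[fr$kept]
#> [1] 1 2 3 5 6 7

res <- run_region_models(m, cohort$cohort, fr$region_id[fr$kept])
res[, c("region_id", "or", "ci_low", "ci_high", "p_raw", "p_fdr", "r2_gain")]
#>   region_id   or ci_low ci_high  p_raw p_fdr r2_gain
#> 1         1 1.58  0.395    6.31 0.5174 0.776 0.01131
#> 2         2 4.33  1.051   17.81 0.0425 0.182 0.11143
#> 3         3 3.60  0.944   13.73 0.0607 0.182 0.09346
#> 4         5 1.18  0.332    4.21 0.7960 0.796 0.00182
#> 5         6 1.71  0.482    6.05 0.4073 0.776 0.01849
#> 6         7 1.34  0.348    5.19 0.6689 0.796 0.00497
```

Reading the output: region 2 is one of the two truly causal regions
(`causal_region_ids`); patients in its high-disconnectivity half have 4.3×
the odds of scoring one mRS grade worse (95% CI 1.05–17.8), and adding the
indicator raises Nagelkerke R² by 0.111 over the covariate-only base
model. At n = 33 nothing survives FDR across six regions — the small-cohort
reality the pipeline is designed to make explicit. `mrs`, ChaCo values and
volumes are all simulated; the truth (effects, cutpoints, causal regions)
is in `cohort$truth`.

The same analysis runs from the command line:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wmhnet.R", package = "wmhnet"))')
Rscript $CLI simulate --out sim --seed 7
Rscript $CLI outcome-model --chaco sim/chaco.csv --cohort sim/cohort.csv \
        --mask-type pwmh --out results.csv
```

or end to end with a YAML config (`run_pipeline()` / `wmhnet.R run`),
which writes every stage output plus a deterministic md5 manifest.

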