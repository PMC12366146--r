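---
title: "Methods: WMH disconnectome scoring and ordinal outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WMH disconnectome scoring and ordinal outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhnet)
```

## The problem

White matter hyperintensities (WMH) are a radiological marker of cerebral
small vessel disease. Beyond their sheer volume, *where* they sit in the
white matter determines which long-range fiber bundles they interrupt, and
therefore which gray-matter regions lose structural connectivity. This
package implements a desk-scale, fully testable version of a lesion-network
pipeline that

1. scores per-region disconnectivity (ChaCo, *change of connectivity*)
   caused by a binary lesion mask projected onto a reference streamline
   connectome,
2. partitions WMH into periventricular (pWMH) and deep (dWMH) components by
   a 10 mm distance-to-ventricle threshold,
3. tests group-level regional disconnection and filters degenerate regions,
   and
4. relates dichotomized regional disconnectivity to an ordinal disability
   outcome (mRS, 0–6) through covariate-adjusted proportional-odds models
   with Benjamini–Hochberg FDR control.

Real applications of this design rely on patient MRI and a tractography
atlas averaged from hundreds of healthy subjects, neither of which can ship
with a package. A seeded synthetic-data module therefore generates every
input the pipeline needs, with the statistical structure the analysis
assumes, so that all downstream stages run in seconds and are verifiable
against independent oracles.

## ChaCo scoring

For region $r$ with connected streamline set
$S_r = \{s : r \in \mathrm{ends}(s)\}$,

$$\mathrm{ChaCo}(r) \;=\;
  \frac{\#\{s \in S_r : s \cap M \neq \emptyset\}}{\# S_r},$$

where $M$ is the lesion mask. A streamline intersects the mask iff any
point of the polyline, resampled at half the minimum voxel edge, falls in a
masked voxel; point-in-voxel uses the inverse affine with rounding to the
nearest voxel index (half-open cells). Both conventions are deterministic
and oracle-checkable: the acceptance suite confirms exact agreement with
exhaustive per-streamline counting on dozens of random connectomes.
Streamlines with both endpoints in $r$ count once. Regions with no
connected streamline yield `NA` ("no information"), deliberately distinct
from 0 ("no damage"), and are excluded downstream.

Raw values are then cleaned with the published rule: values strictly below
0.02 are set to 0 (noise floor of the upstream tool this reimplements),
values above 1 are clamped to 1, and the boundary value 0.02 is kept. The
clamp explains why exact median comparisons with 0 and 1 in the region
filter are meaningful.

## Periventricular vs deep split

A WMH voxel is periventricular when its Euclidean distance (voxel centre to
voxel centre, anisotropy-aware, computed with an exact separable distance
transform) to the nearest ventricle voxel is at most 10 mm, else deep. The
10 mm shell itself is assigned to pWMH — the threshold is quoted in the
literature without stating inclusivity, so the inclusive convention was
chosen and is documented here. WMH voxels inside the ventricle mask
(segmentation slop in real data) go to pWMH with a warning rather than an
error. By construction pWMH and dWMH partition WMH exactly, and volumes add
to machine precision.

## Group statistics and the region filter

"Significantly disconnected at group level" is a one-sample, one-sided
(greater than zero) t-test per region on the cleaned values; the comparator
is the constant 0, so the "unpaired" phrasing used in the clinical
literature maps onto a one-sample test. Zero-variance columns are flagged
degenerate (p = 0 for a positive constant, 1 otherwise) instead of emitting
NaN.

Regions with (almost) complete connection or disconnection are excluded
before outcome modeling: sample skewness $\gamma_1$ outside $\pm 1.3$, or a
column median exactly 0 or 1. Skewness defaults to the adjusted
Fisher–Pearson estimator (the estimator is not named in the source
literature; the plain moment version is available via `adjusted = FALSE`),
and the suite pins both to the direct moment formula at $10^{-12}$.

The cortical/subcortical comparison of mean ChaCo across mask types uses
paired two-tailed t-tests. The pairing unit is genuinely ambiguous in the
source design (reported degrees of freedom suggest region pairing in one
analysis and patient pairing in another), so `compare_mask_types()` exposes
`pairing = "region"` (default; units are stratum regions significantly
disconnected under both mask types of a pair) and `pairing = "patient"`.

## Outcome models

Per region: patients are split at the sample median of the region's ChaCo
(ties and the median itself go to the *low* group, so an odd cohort of 33
splits 17/16); the design is

> high indicator, residualized age, NIHSS, log10 lesion volume,
> residualized log10 WMH volume,

and the model is a proportional-odds (cumulative-logit) regression for the
ordinal outcome, $P(Y \le k \mid x) = \mathrm{logit}^{-1}(\zeta_k -
x^\top\beta)$, so a positive coefficient means higher odds of a *worse*
grade. The high/low convention is fixed here (high = indicator 1, OR > 1 =
worse outcome for the high group); published table footnotes that call the
high group "(reference)" conflict with standard reference-group usage, so
the convention is stated rather than guessed.

Residualization replaces a covariate by its OLS residuals against the
region's *continuous* ChaCo values (configurable to the dichotomized
indicator): the residuals are exactly orthogonal to the disconnectivity
measure in sample. Note the methodological consequence, measured in this
package's calibration study (below): residualizing a *causal* confounder
against the predictor of interest reassigns their shared variance to the
predictor.

The fitter is maximum likelihood with cutpoints kept strictly increasing
through a softplus-increment parameterization, BFGS with analytic
gradients, then Newton polishing on the analytic observed information to
gradient norm $10^{-9}$; covariance is the inverse observed information.
This reproduces `MASS::polr` estimates and SEs (which serve as an
independent oracle in the tests, never as the implementation) and reduces
to ordinary logistic regression within $10^{-6}$ for binary outcomes.
Outcome levels with zero observed counts are collapsed with a warning;
runaway coefficients (|b| > 20) raise an explicit separation error rather
than returning a silently absurd OR — published CIs like 6.51–1,542.21
suggest near-separation behaviour that should be flagged, not reproduced.

Odds ratios use Wald intervals by default
($\exp(\hat\beta \pm z_{0.975}\,\mathrm{SE})$) with profile-likelihood
bounds as an option; p-values are two-sided Wald. Explained-variance gain
is Nagelkerke pseudo-$R^2$ (full minus base model, base = same covariates
without the indicator); the source analyses never name their $R^2$ flavour,
so the choice is recorded in the output metadata and switchable to
McFadden. FDR adjustment is Benjamini–Hochberg across the regions that were
actually fitted for one mask type in one run; failed fits are recorded
per-region and leave the family.

## The synthetic world

Defaults state the cohort the pipeline emulates: 33 patients, age
$\sim N(70.7, 12.2)$ truncated to [40, 95], NIHSS $\sim N(7.8, 3.6)$
rounded and clipped to 1–17, expected WMH volume 15.3 ml split 9.5 ml
periventricular / 5.8 ml deep, stroke lesions 37.9 ml, and a 7-level
ordinal outcome. Between-patient volume variation is lognormal with
sd(log) 0.25 (chosen once as a realistic spread; not stated by any source).

The world is a cube (default 40³ voxels at 2 mm) with a central ellipsoidal
ventricle structure, spherical atlas regions placed by rejection sampling
(cortical near the boundary, subcortical central; hemisphere by the
first-axis midplane), and streamlines drawn as straight lines between
random voxels of two regions, resampled at half-voxel steps with Gaussian
jitter — the simplest geometry that guarantees reproducible mask
intersections. Patient WMH masks are a rim component grown inside the
10 mm periventricular band plus isolated deep spots beyond it; stroke masks
are single blobs. Outcomes come from the generative proportional-odds
model: latent score = `beta_disconnect` × (causal-region mean ChaCo
dichotomized at the sample median) + covariate terms + logistic noise, cut
at fixed, equally spaced cutpoints that are recorded in the returned truth
(fixing the cutpoints removes an unidentifiable degree of freedom from
recovery tests). Per-patient randomness derives from (seed, patient index),
so a cohort can grow without reshuffling earlier patients.

What the generator does *not* emulate: anatomical tract shapes, spatial
autocorrelation of WMH along fiber bundles, MNI-space geometry,
segmentation error, or any dependence of outcome on the stroke mask's
location. A green test therefore establishes the correctness and
calibration of the *computational pipeline*, not clinical validity of the
scientific claims it was designed to probe.

## Numerical choices

* Distance transform: exact separable lower-envelope algorithm with
  per-axis spacing; requires axis-aligned affines (all generated worlds
  comply; rotated real data would need resampling first).
* Intersection resampling step: half the minimum voxel edge; no
  partial-volume weighting.
* Optimizer: BFGS (reltol $10^{-12}$) + Newton polish; init from marginal
  cumulative-logit cutpoints and zero slopes; convergence failures error
  with diagnostics.
* BH adjustment uses the elementary expression `m * p / rank` so that it is
  bit-identical to the step-up definition.
* `clean_chaco` uses strict inequality at the floor, per the published rule
  ("values < 0.02").

## Calibration findings and known limitations

The package's own calibration study (acceptance criterion 6; 200 null
cohorts of 100 patients, `beta_disconnect = 0`) measures a family-level
false-flag rate of 0.095 against the 0.08 bound, and the corresponding test
is deliberately left failing rather than re-tuned. Two measured causes:

1. **Small-sample Wald anticonservatism.** The per-test size of the Wald
   p-value at $\alpha = 0.05$ is 0.074 at n = 33, 0.057 at n = 100 and
   0.054 at n = 200 (1,500 pure-null replicates each). SEs agree with
   `MASS::polr`, so this is a property of the estimator the design
   mandates, not of this implementation. At the cohort sizes where this
   method is applied in practice (n ≈ 33), Wald-based per-region inference
   should be read as anticonservative.
2. **Residualization leak.** With the generator's default volume effect
   (`beta_logvol = 0.5`), setting `beta_disconnect = 0` does *not* make the
   outcome independent of disconnectivity: WMH volume derives from the same
   masks as regional ChaCo, and residualizing it against region ChaCo moves
   their shared variance into the high/low predictor. Removing the volume
   effect lowers the measured flag rate from 0.095 to 0.085, isolating
   roughly one percentage point attributable to the residualization design
   itself.

Permutation-based calibration is clean: Wald p-values for a randomly
permuted predictor are uniform (KS test over 1,000 refits).

Other limitations: the pairwise (region-to-region) disconnectome variant is
out of scope (scoring is regionwise); streamlines carry no per-streamline
weights; profile CIs are computed by repeated constrained refits and are
noticeably slower than Wald; the NIfTI reader covers the common single-file
datatypes only.

## Reproducibility

Every generator is deterministic given `seed`; `run_pipeline()` writes a
manifest with the seed, options and md5 of every output, and rerunning the
same config reproduces identical bytes (gzip output included). The
command-line launcher lives at
`system.file("cli", "wmhnet.R", package = "wmhnet")`.
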