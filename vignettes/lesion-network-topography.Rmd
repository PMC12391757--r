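---
title: "Lesion network topography and stroke outcome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion network topography and stroke outcome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlesion)
```

## The scientific problem

After mechanical thrombectomy for an anterior-circulation large-vessel
occlusion, a large fraction of patients retain disability, conventionally
measured by the modified Rankin Scale (mRS, 0 = no symptoms to 6 = death)
at three months. Clinical eligibility and prognosis currently lean on
volumetric and vascular descriptions of the infarct, yet the consequences
of a lesion plausibly depend less on *which arterial territory* it occupies
than on *which large-scale brain systems* it damages or disconnects.

`netlesion` implements, end to end, an analysis framework for testing that
hypothesis: lesion masks in a common template space are converted into
per-parcel damage features under three parcellations (a vascular-territory
atlas, a distributed resting-state-network atlas, and a white-matter tract
atlas), indirect functional and structural disconnection are estimated from
normative data, penalized regressions of outcome are compared across the
atlas frameworks, and voxel-wise correlates of outcome are localized with
permutation inference. Because suitable patient data cannot be
redistributed, the package ships a synthetic-cohort generator with planted,
configurable effect structure, so every stage of the pipeline can be
validated against a known ground truth.

## Atlas overlap features

For lesion $L$ and parcel $P$ two percentages are computed:

* `lesion_pct` $= 100\,|L \cap P| / |L|$ — how the lesion distributes
  across parcels (sums to at most 100 over parcels);
* `parcel_pct` $= 100\,|L \cap P| / |P|$ — how much of the parcel is
  damaged.

A parcel enters a subject's feature vector only when the overlap involves
at least 5% of the lesion **or** 5% of the parcel (inclusive OR); smaller
overlaps are treated as negligible lesion load and zeroed. The rule is
applied per subject and per parcel — cells are zeroed, columns are never
dropped — so one subject's small overlap cannot silence another subject's
signal.

The design-matrix cell value defaults to `lesion_pct`. The alternative
parameterizations are available through
`build_design_matrix(..., value = "parcel_pct")` (or `"both"`); this
matters because the two metrics answer different questions. `lesion_pct`
describes the lesion's spatial distribution and is insensitive to lesion
volume; `parcel_pct` is proportional to the *fraction of the parcel
destroyed*, which is the quantity the synthetic outcome model (below) is
linear in. The parameter-recovery analyses in the test suite therefore use
`parcel_pct`; with volumes varying twenty-fold across subjects,
`lesion_pct` features are only weakly coupled to a damage-fraction outcome
and recover it poorly by construction, not by defect.

## Indirect functional disconnection

Each lesion is embedded in a normative connectome — a voxel × time array
over a brain mask, standing in for a resting-state fMRI sample of healthy
subjects. The steps are:

1. **Within-lesion connectivity**: Pearson correlations between the time
   series of all lesion voxels inside the brain mask.
2. **PCA reshaping**: the first principal component of that matrix
   identifies the dominant coherent sub-population of lesion voxels. The
   loading vector is oriented so its sum is nonnegative (resolving
   eigenvector sign ambiguity deterministically), negative loadings are
   rectified to zero, and the remainder normalized to sum 1. Lesions of
   one or two voxels, or rank-deficient matrices, fall back to uniform
   weights. Reshaping can therefore reweight but never extend the lesion's
   support.
3. **Seeding**: the seed time series is the weighted mean of the lesion
   voxels' series; the map value at every brain voxel is its Pearson
   correlation with the seed. (Using the first-PC time series instead of
   the weighted mean is a plausible alternative; the weighted mean is the
   simplest contract consistent with seeding a reshaped region, and is
   what the package commits to.)
4. **Thresholding**: values below $r = 0.2$ are zeroed before group-level
   analysis. Maps are kept as raw correlations (no Fisher z), and negative
   correlations are retained until the threshold removes them.

## Indirect structural disconnection

The normative tract set supplies, per tract, a visitation-probability
volume in $[0,1]$ (peak 1 on the core path). A tract is *hit* when the
maximum of its visitation over the lesion voxels reaches 0.5 — the lesion
plausibly interrupts the bundle's core rather than grazing its fringe. The
subject's map value at voxel $v$ is the **maximum** visitation over hit
tracts; the maximum (rather than a sum) keeps the value interpretable as a
probability, which the downstream threshold semantics require. Group
analyses use values strictly above 0.5 (a disconnection probability higher
than 50%). The per-voxel probability construction of real tractogram
databases is proprietary to those resources; the max-over-hit-tracts
contract is this package's defined stand-in and is stated as such.

## Outcome prediction

Five (plus combined) models of the 3-month mRS are compared, all with the
same machinery: Lasso regression with the L1 penalty selected by
leave-one-out cross-validation over 100 log-spaced values from $10^{-5}$
to $10^{5}$ by negative mean squared error, ties resolved toward the
larger (sparser) penalty. Within each training fold, features are
standardized using that fold's statistics only, so no information about
the held-out subject leaks into its prediction. The headline $R^2$ is
**out of sample** — computed from the held-out predictions — because an
in-sample $R^2$ after a cross-validated selection would overstate
performance; the in-sample variant is also reported. `loo_sd` is the
standard deviation over folds of the squared held-out error. mRS is
treated as a numeric target (as a Lasso regression implies); ordinal
models are out of scope. The clinical benchmark uses age, sex and
admission NIHSS; combined models concatenate atlas features with those
covariates and report the gain over the atlas-only model.

## Voxel-wise inference

The per-voxel statistic is the Pearson correlation of subjects' map values
with the outcome, converted to $t = r\sqrt{(n-2)/(1-r^2)}$ (capped at
$10^6$ as $|r| \to 1$; the cap is order-preserving). Voxels where fewer
than 5 subjects have nonzero values, or with zero variance, are excluded
from the analysis mask rather than errored — correlations over
near-constant columns are noise.

TFCE integrates cluster extent over all supra-threshold heights:
$\mathrm{TFCE}(v) = \sum_{h = dh, 2dh, \dots}^{\max t} e_h(v)^{E}\, h^{H}\, dh$,
with $E = 0.5$, $H = 2$, 26-connectivity and 100 integration steps — the
field-standard parameterization. The discrete integral is computed exactly
by an incremental union-find over descending thresholds (compiled code);
the test suite checks it to $10^{-9}$ relative error against an
independent threshold-loop oracle built on igraph components.

Family-wise error is controlled by the max-statistic permutation scheme:
the outcome vector is fully permuted across subjects (exchangeable under
the null of no association), the maximum TFCE over the mask is recorded
per permutation, and $p_{\mathrm{FWE}}(v) = (1 + \#\{\max \ge
\mathrm{TFCE}_{obs}(v)\})/(m+1)$ — the add-one estimator, flooring
p-values at $1/(m+1)$. Positive and negative contrasts are separate runs
on sign-flipped statistics and swap exactly when the maps are negated.
When no fixed `dh` is supplied, each map (observed or permuted) uses its
own `max/100` step, the convention of the standard permutation tools;
oracle comparisons pass a fixed `dh`. Nuisance covariates are not
regressed out of the voxel-wise model; a design-matrix extension is the
natural hook for that.

## What the synthetic generator emulates

* **Geometry**: an ellipsoidal brain mask on a 24×28×24 voxel grid (2 mm
  spacing). This is deliberately far coarser than 1–2 mm template grids;
  it preserves every structural property the methods rely on (contiguity,
  laterality, distributed networks, corridors) at tractable cost.
* **Vascular-like atlas**: 10 contiguous Voronoi wedges partitioning the
  mask — territories are compact and boundary-mismatched to the networks.
* **Network-like atlas**: 7 networks, each realised as four disjoint
  Voronoi patches (two per hemisphere). The multiplicity matters: with
  one compact patch per hemisphere, a territory atlas resolves networks
  almost perfectly and the vascular/network comparison degenerates;
  distributed patches recreate the essential property that arterial
  territories mix functional systems.
* **Connectome**: voxel time series
  $\sqrt{c}\, g_{\mathrm{net}(v)} + \sqrt{1-c}\, \varepsilon_v$ with
  standard-normal latent signals and noise, so same-network voxels
  (including across disjoint patches) correlate at $c$ (default 0.6) and
  cross-network voxels at 0. Empirical correlations converge to these
  values as the series lengthens (checked at 2000 timepoints, tolerance
  0.05).
* **Tracts**: corridors joining the two patches of a network through
  (possibly bent) polylines between patch centroids, visitation 1 on the
  core decaying linearly to 0 at 3 voxels.
* **Cohort**: 70 subjects; lesions are 6-connected random-growth blobs
  confined to one hemisphere (left with probability 40/70), volume
  log-uniform in 20–400 voxels. Latent outcome
  $= \beta_0 + \sum_p w_p f_p + \beta_a(\mathrm{age}-73) +
  \beta_s \mathrm{sex} + \beta_n \mathrm{NIHSS} + \mathcal N(0,\sigma)$,
  where $f_p$ is the fraction of network parcel $p$ lesioned; mRS is the
  latent outcome cut at fixed points 0.5, 1.5, …, 5.5 and clipped to 0–6
  (generated ordinally, fitted numerically — mirroring how a Lasso treats
  the scale). Defaults ($w = 16, 12$ on two networks; NIHSS effect 0.15
  per point with NIHSS itself increasing in lesion volume; noise SD 1)
  place the default cohort in a realistic effect-size regime: atlas-model
  out-of-sample $R^2$ roughly 0.15–0.45, clinical benchmark roughly
  0.3–0.5, mRS spanning the full 0–6 range.

What the generator does **not** emulate: haemodynamics, anatomically
realistic territory shapes, CT-vs-MRI delineation differences (one
modality-agnostic mask per subject), spatial autocorrelation of fMRI
noise, and distance-dependent connectivity. Passing tests therefore
demonstrate the *statistical machinery* is correct and well calibrated on
data with the stated structure — not that any particular clinical effect
size generalizes to real cohorts.

## Numerical choices and degenerate inputs

* Mask binarization threshold 0.5 (masks are nominally binary; 0.5 is
  symmetric). Nearest-neighbour resampling breaks exact half-way ties
  toward the lower index; voxel indexing is 0-based and world space is
  RAS mm, one fixed convention throughout.
* All voxel-wise analyses run on a single analysis grid; per-feature
  native grids are not mixed within one inference.
* Empty lesions yield all-zero features and empty retained sets; constant
  outcomes make $R^2$ undefined and are reported as 0 with
  `r2_defined = FALSE`; constant per-network scores are reported as
  $r = 0$ with a `degenerate` flag.
* Lambda-grid ties select the larger penalty; `glmnet` solves each
  penalized fit with threshold $10^{-10}$ so selection is deterministic.
* Every generator and the permutation engine are exactly reproducible
  from their seeds; `run_all` fans one master seed out to per-stage
  sub-seeds by fixed offsets, so stages can be re-run in isolation.

## Problem sizes used by the shipped checks

The test suite runs the full pipeline at its default scale (70 subjects,
24×28×24 grid, 500 permutations — about half a minute per run) and the
calibration studies at reduced scale chosen for a desk machine: 200 null
cohorts of 30 subjects on a 16³ grid at 500 permutations for family-wise
error calibration, 20 replicate cohorts for the planted-effect and
atlas-ordering checks, and 8³/12³ instances for the exact counting and
TFCE oracles. `scripts/acceptance.R` regenerates the default cohort from
a supplied seed and recomputes the headline quantities.

## Known limitations

* The PCA "reshaping" step and the max-over-hit-tracts construction are
  defined contracts standing in for unpublished or proprietary formulas
  of the corresponding clinical toolkits.
* Lasso retains one of several highly correlated predictors arbitrarily;
  coefficient identities (as opposed to predictive performance) should be
  interpreted cautiously.
* The permutation scheme assumes full exchangeability of the outcome; no
  covariate-adjusted (e.g. Freedman–Lane) scheme is implemented.
* The 17-network variant of a functional parcellation is represented only
  through the configurable network count of the generator.
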