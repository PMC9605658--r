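---
title: "Comparing PET lesion-segmentation thresholds on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing PET lesion-segmentation thresholds on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmtv)
```

## Motivation and model

Volumetric FDG-PET parameters — metabolic tumor volume (MTV, mL) and total
lesion glycolysis (TLG = MTV × SUVmean) — are candidates for risk
stratification in Hodgkin lymphoma, but they are only as reproducible as the
delineation rule that produces the lesion mask. `petmtv` implements the four
threshold rules most often compared in this setting and the statistical
battery used to judge their agreement and their association with treatment
response.

All four methods share one mechanism. Given an operator-provided lesion
query (a seed voxel and a search VOI bounding the nodal site), a method
computes a scalar SUV threshold, keeps the voxels of the search VOI at or
above it, and retains the 26-connected component containing the seed:

* **V41%** — threshold `0.41 × SUVmax`, with SUVmax evaluated *within the
  search VOI*, never globally: each site is scaled to its own peak.
* **V2.5** — absolute threshold SUV 2.5.
* **Vliver** — the site is *eligible* only if `SUVmax / SUVmean(liver) >
  1.5`; eligible sites are thresholded at `1.5 × SUVmean(liver)`. An
  ineligible site yields an empty mask flagged "below liver criterion" — a
  result, not an error, because post-therapy residual assessment depends on
  it.
* **AM** (adaptive) — let `Imax` be the site SUVmax and `I(mean)` the mean
  SUV over the 70 %-of-Imax isocontour (again the seed's connected
  component, restricted to the search VOI). The threshold is
  `0.15 × I(mean) + SUVmean(liver)`: a fixed fraction of the lesion's core
  intensity on top of a liver-derived background estimate. The rule is
  applied in a single pass; on a perfectly uniform lesion the isocontour is
  the whole lesion and the threshold reduces to `0.15 × uptake + liver`.

From each mask the package extracts SUVmax, SUVmean, SUVpeak, MTV and TLG;
multi-lesion scans are aggregated with the total-MTV convention (MTV and TLG
summed, scan SUVmean = ΣTLG/ΣMTV, SUVmax the maximum, SUVpeak that of the
hottest lesion). Percentage changes from baseline are
`100 × (follow-up − baseline)/baseline`; a zero baseline leaves the change
undefined (`NA`, dropped listwise downstream) rather than zero.

## Numerical conventions

Choices that affect voxel-level results, all fixed package-wide:

* Voxel membership — in lesions, VOIs and masks alike — is decided by the
  voxel *centre* lying inside the analytic shape, so phantom truth volumes
  and measured MTVs converge together as spacing shrinks.
* Voxel inclusion is inclusive (`SUV ≥ threshold`) for every method; the
  strict ">" of the liver rule is read as the *eligibility ratio*, not voxel
  strictness. On continuous-valued data the difference has measure zero; one
  convention keeps the mask-nesting property exact. Whether the liver rule
  should *also* threshold voxels at 1.5 × liver (our default) or use the
  ratio purely as a positivity criterion (voxels then cut at the liver mean)
  is genuinely underdetermined in practice, so both behaviours sit behind
  `segment_vliver(rule = )`.
* Connectivity is 26-neighbour (faces, edges, corners), the standard for 3D
  hot-spot delineation; 6-connectivity is available for sensitivity checks.
  The flood fill is layer-vectorized and independent of visitation order.
* The AM isocontour is confined to the search VOI, as is every mask, so
  adjacent nodal sites cannot merge through a bridge outside the operator's
  region.
* SUVpeak is the mean over a 1 mL sphere (radius ≈ 6.204 mm) centred on the
  hottest *masked* voxel; the sphere itself is an image neighbourhood and may
  extend outside the mask, and is clipped (with a warning) at the grid
  boundary. Ties for the hottest voxel are broken toward the tied voxel
  nearest the mask centroid, then by lowest linear index: on a noiseless
  uniform lesion the first-index rule would park the sphere on the lesion
  edge and average in background, whereas the centroid rule returns the
  field value, which is the only defensible answer for a constant lesion.
  Real (noisy) data have no exact ties, so the two rules coincide there.
* Empty masks are valid results everywhere (metrics all zero), because
  end-of-therapy scans routinely clear completely.

## Deauville scoring and dichotomization

Follow-up scans are graded on the 5-point scale: DS 1 no residual uptake;
DS 2 residual ≤ mediastinal blood pool; DS 3 ≤ liver; DS 4 moderately above
liver; DS 5 markedly above liver or new disease. "Moderately vs markedly"
has no universal numeric boundary; we quantify it as `ds5_factor ×
SUVmean(liver)` with default 2.0, exposed as configuration. The score is
per-scan and method-independent: residual uptake is taken from the masks of
one reference segmentation (Vliver by default, configurable), DS 1 meaning
no residual mask at all. For the regression stage each cut s ∈ {2,…,5} is
binarized as "achieved DS ≤ s" by default; the alternative "DS = s exactly"
reading is implemented behind `ds_outcome = "exactly"`, since published
response tables are ambiguous between the two.

Note one interaction: with Vliver as the reference segmentation, a site
only produces a residual mask when its SUVmax exceeds 1.5 × liver, so
measured scores concentrate on {1, 4, 5}; DS 2–3 arise only for other
reference choices. The ground-truth DS of the generator (below) spans the
full scale, and the rule set itself is tested across all five grades.

## The phantom generator

The generator is the package's substitute for patient scans: it renders what
the pipeline needs to be *validated* — not a scanner simulation. A phantom is
a uniform background (default SUV 0.7) holding a liver sphere (SUV 2.0), a
mediastinal blood-pool box (SUV 1.5) and spherical or ellipsoidal lesions,
rasterized by voxel centre, convolved with an isotropic Gaussian PSF
(default FWHM 6 mm, the resolution class of clinical reconstructions) and
degraded with additive Gaussian noise clipped at zero (default SD 0.15 SUV).
Heterogeneous lesions fall linearly from peak uptake at the centre to
(uptake − amplitude) at the rim; this single knob creates the
relative-vs-absolute threshold divergence that drives the agreement
analysis. Poisson counting noise, scatter, attenuation and reconstruction
artifacts are deliberately out of scope — so passing tests demonstrate
algorithmic correctness and method-contrast behaviour, not performance on
raw clinical data.

A cohort draws per-patient baselines by jittering the template lesions
(uptake × U(0.8, 1.3), radius × U(0.75, 1.25)) — without this, every patient
would be identical and correlation structure would be degenerate — and then
applies a response model: at PET2, uptake shrinks by U(0.25, 0.70) and
radius by U(0.40, 0.80) with a 15 % chance of early complete clearance; by
PET3, 70 % of patients clear completely and the rest retain residual disease
at uptake U(0.20, 0.60) and radius U(0.30, 0.70) of baseline (capped at the
PET2 factors so response is monotone). The PET3 mixture was chosen so the
end-of-therapy cohort shows a spread of Deauville outcomes — a cohort whose
residual disease is all invisible would make the response-regression stage
structurally empty. Clearance is independent of baseline burden by design
(the association tests plant their own effects); ground-truth DS is computed
from the known residual peak uptake against the template's true reference
values, with clearance ≡ DS 1. All randomness derives from one master seed
with fixed per-patient offsets, so cohorts are bit-reproducible.

On follow-up scans the pipeline re-uses the baseline sites as queries but
delineates a site only if its search-VOI SUVmax exceeds 1.5 × liver SUVmean
(the same criterion the liver rule uses for eligibility). Without this gate
the relative V41% threshold — 41 % of whatever the search VOI's maximum is —
would happily contour background noise on a cleared site, which no operator
workflow would do.

## Statistics

Agreement between method pairs is summarized per parameter (SUVmean, MTV,
TLG) and column (absolute values at PET1/PET2/PET3; percent changes to PET2
and PET3): Pearson rho with its exact t-test p-value and the OLS line (via
`stats::cor.test`/`stats::lm`), and Bland–Altman bias, SD of differences
(n − 1), and limits of agreement bias ± 1.96 SD (the multiplier is
configurable; plots draw both the ±1 SD and ±1.96 SD lines). Differences are
taken first-minus-second in the pair's printed order. Cells with fewer than
3 complete pairs or zero variance are reported with a reason, never dropped.
No multiplicity correction is applied to the reported p-values; a
Benjamini–Hochberg column is emitted alongside for reference only.

The response analysis regresses each dichotomized DS column on each
method × parameter, as baseline absolute values and as percent changes, with
`stats::glm` (binomial). Odds ratios are reported per unit *and* per SD of
the predictor — volumetric predictors span hundreds of mL, so per-unit ORs
round to 1 and the per-SD column is the readable one. Wald 95 % CIs use
exp(coef ± 1.96 SE); separation and non-convergence are detected (including
|coef| exploding on the standardized scale) and flagged, and impossible
cells (single-class outcome, zero-variance predictor, too few patients) are
reported with their reason, mirroring the dash cells of published tables.

## Problem sizes and validation

The test suite validates each stage against independent oracles: analytic
sphere volumes and a closed-form Gaussian-blurred-sphere centre value for
the generator; naive full-grid scans with an explicit-stack flood fill for
segmentation and metrics (32³ grids); the dual-formula Pearson identity, the
closed-form 2×2 odds ratio, planted-parameter recovery (logistic slope 0.8
at n = 5000, Bland–Altman SD at n = 10⁴) and 2000-replicate null
calibrations for the statistics. Mask-nesting under threshold order is
checked exhaustively across 200 randomized phantoms. The default study size
used in tests and in `scripts/acceptance.R` is 20 patients × 3 timepoints on
a 56 × 56 × 44 grid at 3 mm spacing — large enough for stable agreement
patterns (the AM–Vliver pair correlates most strongly for MTV and the V41%
pairs show the widest limits of agreement on heterogeneous-lesion cohorts),
small enough to re-run casually; end-to-end byte-reproducibility is asserted
on a 10-patient run.

## Limitations

* Phantom realism ends at Gaussian blur + Gaussian noise on piecewise-smooth
  activity; no scanner physics, no respiratory motion, no reconstruction
  nonlinearity.
* The liver reference VOI is an input (default: 3 cm-diameter sphere), not
  auto-segmented; its placement is operator work in clinical tools, and the
  measured liver mean is partial-volume biased on small phantoms.
* The AM rule is the single-pass closed form; iterative adaptive variants
  are out of scope.
* Deauville scoring here is a quantitative surrogate for a visual scale; the
  DS4/DS5 boundary is an explicit parameter, not a clinical standard.
* No survival endpoints, ROC cutoff optimization, or multivariable models.
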