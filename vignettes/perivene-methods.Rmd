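---
title: "Methods: perivenous diploic-space and parasagittal-dura volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perivenous diploic-space and parasagittal-dura volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

On contrast-enhanced T1-weighted head MRI acquired with motion-sensitized
driven equilibrium (MSDE), flowing blood in vessel lumens is
signal-suppressed while gadolinium that has distributed into slow or static
fluid compartments is bright. Hours after contrast administration, a bright
sheath appears around the dark diploic veins inside the skull diploe, and
the parasagittal dura (PSD) flanking the superior sagittal sinus (SSS)
enhances as well. Both compartments are candidates for routes of
cerebrospinal-fluid and waste excretion, so their volumes — and how those
volumes relate to age and sex — are of neuroradiological interest.

`perivene` implements the measurement rules for both compartments as a
reproducible pipeline:

* **perivenous diploic space (DV):** voxels whose signal strictly exceeds a
  predetermined threshold, minus operator-supplied exclusion masks
  (reticular marrow-like enhancement of uncertain origin), restricted to
  transverse slices strictly above the superior border of the lateral
  ventricles, keeping only in-plane components whose inscribed-disc
  diameter is at least 2 mm;
* **PSD:** the same threshold rule, intersected with the 3D Euclidean band
  up to 10 mm from the outer edge of the SSS, the same slice restriction,
  with parenchymal and intra-skull enhancement removed by caller-supplied
  brain and skull masks (no diameter filter — that rule applies to the DV
  compartment only);
* **normalization:** each volume (mm^3^) divided by the intracranial volume
  (cm^3^), giving mm^3^ cm^-3^.

No imaging data accompany the reference protocol this models, so a synthetic cranial
phantom and a calibrated synthetic cohort stand in for patients; every
downstream stage is tested against ground truth or an independent oracle.

## Segmentation: definitions and numerical choices

**Threshold.** `threshold_mask()` is strict (`intensity > threshold`). The
"predetermined value" is a required input; `otsu_threshold()` is offered as
a data-driven suggestion but is never applied silently.

**Slice restriction.** "Above the superior border of the lateral
ventricles" is read exclusively: `restrict_above_plane(mask, z_min)` keeps
axial indices `> z_min` (1-based), so the border slice itself is excluded.
Users matching a different convention on real data can pass `z_min - 1`.

**The ≥ 2 mm diameter rule.** The source protocol does not say whether the
criterion was evaluated in 2D or 3D, nor which connectivity the tooling
used. `perivene` defines diameter *per transverse slice*: 8-connected 2D
components are kept iff twice the maximum of the in-plane Euclidean
distance transform (EDT) to the background — the maximum inscribed-disc
diameter, computed with physical spacing so anisotropic grids are handled
correctly — reaches `min_diameter_mm`. Retention is inclusive at exactly
the threshold ("diameters of ≥ 2 mm"). Rationale: the ROIs are drawn on
transverse images and the axial spacing (1 mm) is coarse relative to a 2 mm
criterion; a 3D variant (26-connected components, 3D EDT) is available via
`mode = "3d"` but is not the default. The EDT is exact (separable
lower-envelope algorithm in C++), and distances are measured between voxel
centers; components touching the grid border can therefore have their
diameter overestimated by up to one voxel.

**The 1 cm SSS band.** `sss_band()` uses the 3D Euclidean distance to the
SSS mask, anisotropy-aware, and excludes the SSS itself ("from the outer
edge"). Whether the original measurement enforced the band in 3D or
slice-wise is unstated; 3D was chosen because "within 1 cm" is a physical
distance.

**Manual steps as masks.** The operator's manual exclusions (reticular
regions for DV; parenchymal and intra-skull enhancement for PSD) are
modeled as explicit mask subtraction. No automatic reticularity classifier
is attempted — the distinction is visual in the source protocol, and hiding
it inside a heuristic would make the pipeline less auditable, not more.

**Chain properties.** Every stage removes voxels and never adds them, so
measured volume is monotone non-increasing along the chain, non-increasing
in the threshold, and the diameter filter is idempotent. These are asserted
as property tests, not just documented.

## Intracranial volume: a surrogate, on purpose

The original protocol ran an external brain-extraction tool (fractional
intensity 0.30) and took its mask volume. That tool is third-party software
the reference protocol *called*, not an algorithm it *defined*, and the analysis depends
only on a consistent denominator. `estimate_icv()` therefore implements a
documented surrogate: threshold (fixed, or Otsu over nonzero voxels) →
largest 26-connected component → morphological closing with a Euclidean
ball (default 4 mm, enough to close sulci-scale gaps and absorb the dural
gap and sinus) → interior hole fill. The result mask is exposed for the
same visual QC the original protocol relied on; no automatic QC gate is
defined because the source defines none. The closing is implemented through
the exact EDT, so the same physical radius behaves identically on any grid.

Two discrete-morphology caveats, verified in tests: closing is extensive by
definition, so the surrogate inflates the volume by a sub-voxel boundary
shell (the coarse-vs-fine consistency test bounds this at < 5% for
head-sized objects); and a skull table thinner than about two voxels can
rasterize with diagonal gaps through which bright diploic structures
26-connect to the intracranial compartment — synthetic heads used for ICV
testing keep the inner table at ≥ 2 voxels.

## The synthetic phantom

`build_phantom()` paints a disjoint partition of compartments — air, skull
tables, diploe, brain, CSF/dural gap, vein sheath, vein lumen, PSD, SSS —
as nested ellipsoid shells plus capsule-rasterized tubes, then assigns
compartment-mean intensities and optional additive Gaussian noise. Because
the partition is disjoint, truth masks are exact and the noiseless image is
exactly piecewise constant, which is what makes voxel-for-voxel recovery
tests meaningful.

Default geometry (a head-sized vault at 0.625 × 0.625 × 1 mm): skull outer
semi-axes 54/58/72 mm, 1.5 mm tables around a 7 mm diploe, 4 mm dural gap,
four diploic-vein arcs at mid-diploe depth with a 0.6 mm suppressed lumen
inside a 2.4 mm bright sheath, a 4 mm-radius midline SSS tube tangent to
the inner table, and four 2.6 mm PSD blobs in the dural gap beside the SSS.
The sheath thickness is chosen so every sheath cross-section comfortably
exceeds the 2 mm criterion — by definition the measured perivenous spaces
are the ≥ 2 mm ones, and a phantom whose target structure straddled its own
inclusion criterion would make ground-truth comparison meaningless. The
intensity ordering (sheath/PSD ≫ CSF/brain > diploe > tables > lumen) is
enforced at construction.

What the phantom deliberately does **not** emulate: Rician noise statistics
(noise is Gaussian; compartment contrast, not the noise law, drives the
measurements), bias fields, partial-volume spectra, k-space artifacts, and
skull-base anatomy below the ventricles. A green phantom test therefore
establishes that the *rules* are implemented correctly on geometry of the
right scale — not that the pipeline segments real tissue.

## The synthetic cohort

Calibration constants live in one versioned file
(`inst/extdata/cohort_calibration.json`) read by `default_calibration()`.

**Marginals.** Measured volumes were non-normally distributed, reported as
medians with IQRs; the generator uses log-normal marginals with
`exp(mu)` equal to the target median and `sigma` set from the IQR ratio,
`sigma = log(q75/q25) / (2 * qnorm(0.75))`. The printed quartiles are not
exactly log-symmetric about the printed median, so a log-normal cannot hit
the median and both quartile endpoints at once; the generator reproduces
the median exactly and the quantile *span*.

**Age dependence.** Ages are uniform on [14, 84] (the printed range; no
histogram is available). Rank dependence between age and each corrected
volume comes from a Gaussian copula whose Pearson parameter is
`r = 2*sin(pi*rho_s/6)`, so the implied Spearman coefficient equals the
calibration target (−0.330 for DV, +0.385 for PSD) exactly in the copula;
the DV–PSD cross-dependence is set to zero, matching the null cross-finding.

**Sex effect.** No per-sex medians are printed, only Mann–Whitney
p-values. The male/female multiplicative shifts (1.97 for DV, 1.73 for
PSD) were derived once, analytically, by inverting the Mann–Whitney normal
approximation at the printed p-values (0.047 and 0.014; n = 45 vs 53)
given the log-scale SDs implied by the printed IQRs. The shift is split
symmetrically (`sqrt(ratio)` up for men, down for women) so the overall
median is preserved. A side effect worth knowing: the shared sex factor
induces a small (≈ 0.05) residual rank correlation between the two
corrected volumes — far below detectability at n = 98, consistent with the
reported null.

**ICV.** The corrected and uncorrected printed medians imply two different
ICV medians (≈ 1550 cm^3^ from DV, ≈ 1364 cm^3^ from PSD), so no single
denominator reproduces both. The corrected volumes are what the acceptance
checks target, so they are generated directly; ICV is log-normal with
median 1450 cm^3^ (≈ the geometric mean of the two implied values and a
typical adult ICV), spread `sigma_log = 0.08`, and a 1.12 male/female
ratio; uncorrected volumes are corrected × ICV and land within ~7% of the
printed uncorrected medians.

**Rater tables.** On the Ln(x+1) scale, measurements decompose as
subject + rater-bias + residual Gaussian components. The subject variance
is the log-scale variance implied by the printed uncorrected IQR (the
reliability analysis ran on raw volumes); the remaining variance is split
equally between rater bias and residual so the population
ICC(2,1) = s²~subject~ / (s²~subject~ + s²~rater~ + s²~residual~) equals
the printed 0.971 (DV) / 0.997 (PSD).

## Statistics

* **Normality gate.** The Kolmogorov–Smirnov statistic is computed against
  a normal with the sample's own mean and SD, so the naive KS null is
  anticonservative; `ks_normality()` uses Lilliefors-corrected p-values —
  by default the deterministic Dallal–Wilkinson analytic approximation
  (the behavior of common `lillie`-style implementations), with a seeded
  Monte-Carlo null available behind `p_method = "monte-carlo"`. The null
  rejection rate at α = 0.05 is verified at 5% in tests.
* **Dispatch.** `method = "auto"` uses Pearson / Welch-t only when *both*
  samples pass the gate, otherwise Spearman / Mann–Whitney — the same
  gating the source analysis describes. All tests are two-sided at
  α = 0.05 with no multiplicity correction; ties take average ranks
  everywhere; the t test is Welch (the source does not specify equal
  variances, and assuming them would be strictly worse).
* **Exactness.** Correlation p-values use full permutation enumeration for
  n ≤ 10 and the t-approximation above; Mann–Whitney uses the exact null
  rank-sum distribution (dynamic program, verified against full `combn`
  enumeration) when `min(n, m) ≤ 8` with no ties, else the normal
  approximation with continuity and tie correction.
* **ICC(2,1).** Two-way random effects, absolute agreement, single
  measures, from the ANOVA mean squares, with the standard F-based 95% CI;
  the CI method is a package choice since the source names none. With
  `transform = "ln1p"` the matrix is Ln(x+1)-transformed first. One
  statistical subtlety: with k = 2 raters the rater-bias component has a
  single degree of freedom, so the ICC estimate from *one* table does not
  concentrate as subjects increase — only its mean over independent tables
  converges to the population value. The tests and the acceptance report
  therefore average over many seeded tables of the original 10-subject ×
  2-rater design.

## What the acceptance evidence does and does not establish

The cohort/rater criteria show that, when the generator is calibrated to
the published summary statistics, the full generator → measurement →
statistics path recovers those statistics within stated tolerances. That
validates the statistical machinery and the calibration jointly; it cannot
validate the imaging stages against patient data (none were deposited).
The imaging stages are instead validated by exact-oracle equivalence
(brute-force inscribed-disc search, brute-force distance scans, exhaustive
rank enumeration) and by phantom ground-truth recovery within
discretization tolerances (10% noiseless, 15% at 5% noise).

## Known limitations

* NIfTI-1 support is intentionally minimal: single-file `.nii`/`.nii.gz`,
  common datatypes, sform/qform affines, RAS reorientation by axis
  permutation/flip. Oblique affines are not resampled — the slice
  restriction assumes the third axis is axial.
* No registration or inter-subject resampling; no DICOM.
* The reticular-versus-perivenous distinction is operator-supplied, as in
  the source protocol.
* `rasterize_tube()` requires an axis-aligned grid.
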