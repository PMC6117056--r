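---
title: "Quantifying cranial-caudal heterogeneity of emphysema from CT and oxygen-enhanced MRI"
author: "lunghetero"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cranial-caudal heterogeneity of emphysema from CT and oxygen-enhanced MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lunghetero)
```

## The problem

Emphysema destroys alveolar walls, which shows up on CT as abnormally
low-attenuation lung tissue and on oxygen-enhanced MRI (OEMRI) as reduced
signal enhancement when the subject switches from room air to 100%
oxygen. Two whole-lung severity indices are standard: the low attenuation
volume percentage (LAV%) on CT and the mean relative enhancement ratio
(MRER) on OEMRI. But two lungs with the same whole-lung burden can
distribute it very differently along the cranial-caudal axis, and that
spatial heterogeneity carries independent information about gas transfer
(DL~CO~) and arterial oxygenation (PaO~2~). This package computes both the
whole-lung indices and their cranial-caudal heterogeneity counterparts
(SD-LAV, SD-RER), and provides the statistical layer that relates them to
pulmonary function in a two-group (COPD vs control) design.

## CT densitometry

A chest CT volume with lung and trachea masks is processed in four steps.

1. **Tracheal-air calibration.** Scanner offset is removed by an additive
   shift that brings the mean HU inside the trachea mask to exactly
   -1000 HU (tracheal air is the purest in-scan air reference). An
   additive shift is the minimal model: it preserves HU differences and
   therefore threshold semantics. Shifts beyond 100 HU trigger a warning,
   since they usually mean the trachea mask is wrong. The applied shift
   is recorded in the result.
2. **Thresholding.** A lung voxel is low-attenuation if its calibrated HU
   is strictly below -960 HU. The threshold is a parameter
   (`threshold`), but -960 with a strict `<` is the default; voxels
   outside the lung mask never count.
3. **Isovolumetric partitioning.** Lung voxels are ordered cranial to
   caudal (slice-major, row-major within a slice) and cut into 12
   partitions of equal voxel count. The division remainder goes to the
   earliest partitions, and voxels of a boundary slice fill the earlier
   partition until its quota is met — a fully deterministic rule, so
   results are bit-reproducible. Equal voxel count is a true equal-volume
   split under uniform spacing; with isotropic z-spacing, counting voxels
   and weighting by slice thickness coincide. The first and last
   partitions are excluded from heterogeneity summaries because the lung
   apex and base are dominated by partial volume averaging.
4. **Summaries.** Whole-lung LAV% is computed over the *entire* lung
   (end partitions included). SD-LAV is the standard deviation of the
   per-partition LAV% over the 10 kept partitions. The sample (n-1)
   denominator is used by default; the convention is rarely reported in
   the literature, so it is a documented, configurable choice
   (`denominator = "population"` gives the n form).

## OEMRI quantification

The emulated exam acquires repeated coronal T1-weighted frames over three
sections (anterior, central, posterior) while the subject breathes room
air for 5 minutes, 100% oxygen for 5 minutes, then room air again.
Dissolved molecular oxygen is weakly paramagnetic, so oxygen wash-in
raises the T1-weighted lung signal by a few tens of percent.

The per-pixel index is the relative enhancement ratio

$$\mathrm{RER} = \frac{|SI_\mathrm{enhanced} - SI_\mathrm{baseline}|}{|SI_\mathrm{baseline}|} \times 100,$$

which the absolute value makes non-negative by construction. Protocols
rarely state which frames represent the two conditions; this package
averages the steady-state tails — the last 50% of the room-air phase and
the last 50% of the oxygen phase (`windowFraction`, configurable) — which
skips the wash-in transient. Pixels whose baseline magnitude falls below
a floor (default 5% of the median ROI baseline) are excluded from the ROI
and counted, preventing division blow-ups.

MRER is the pixel-weighted mean over the pooled lung-ROI pixels of all
three sections (no per-section averaging first; larger sections therefore
contribute proportionally — a documented choice where conventions
differ). SD-RER pools the ROI pixels of all sections on a common physical
cranial-caudal coordinate, splits them into 10 equal-count partitions
with the same quota rule as the CT scheme but *without* end exclusion
(the protocol summarizes 10 direct parts; `excludeEnds = TRUE` mimics the
CT convention for sensitivity analysis), and takes the sample SD of the
10 partition means.

## Cohort statistics

- **Two-group comparison** (`compareGroups`): Shapiro-Wilk normality per
  group at alpha 0.05 (the gate's alpha is a choice, exposed as an
  argument); if either group fails, Mann-Whitney U, otherwise a t test.
  The Welch (unequal-variance) form is the default because it is the
  safer general choice; `welch = FALSE` restores the classic Student
  form. Summaries report median (25th, 75th) as well as mean and SD.
- **Correlation** (`correlateVars`): Pearson by default, Spearman when
  either variable fails the per-variable normality gate.
- **Stepwise regression** (`stepwiseRegression`): bidirectional p-value
  stepwise on z-scored variables, add at p < 0.05, drop at p > 0.10 —
  the classic thresholds, exposed as `pEnter`/`pRemove` since software
  defaults differ. Because everything is standardized, coefficients are
  standardized betas, and with a single selected predictor the beta
  equals the Pearson correlation (an identity the tests verify to
  1e-9). Near-collinear candidates (auxiliary R² > 0.999 against the
  included set) are skipped with a warning. No multiple-testing
  correction is applied by default, matching common practice in this
  literature.

## The synthetic data generator

No patient images ship with the package; every stage is exercised on
synthetic data with known ground truth.

**CT phantom.** Two ellipsoidal lungs and a cylindrical trachea in a
configurable grid (default 24 x 24 x 30 voxels at 2 mm — small enough
that a full test sweep runs in seconds, large enough for ~3,400 lung
voxels and 12 stable partitions). Emphysema is laid down as ~2.5 mm
spherical clusters inside the lung until the labeled fraction is within
0.5 percentage points of the target. The cranial-caudal distribution is
controlled by a single dial, `gradientStrength`, a linear tilt on the
cluster-center density (0 homogeneous, positive caudal-dominant). HU
values are drawn from parenchyma and emphysema Gaussians chosen to
straddle the -960 HU threshold (-860 ± 35 and -985 ± 8), the trachea is
air at -1000 ± 2 HU, and a `globalHUOffset` emulates scanner
miscalibration for the calibration stage to undo. With the HU noise set
to zero the threshold mask equals the label mask exactly, which is what
makes parameter-recovery tests sharp.

Cluster placement deserves a note. Independent random placement leaves
the realized axial profile — and hence SD-LAV — with sampling noise of
several percentage points at this grid size, large enough to drown a
moderate gradient; the heterogeneity dial would then be noisy and
non-monotone for many seeds. The generator therefore *stratifies* the
same tilted density: per-slice emphysema quotas are computed from the
density, each cluster is centered on the slice with the largest relative
deficit, in-slice positions follow a per-slice randomized golden-ratio
sequence (so emphysema spreads evenly along the order used to split
boundary slices between partitions), and a final single-voxel
"micro-lesion" pass lands every slice on its quota. The realized
distribution is the same tilted density, but its variance is small
enough that SD-LAV responds smoothly and monotonically to the dial —
a property the acceptance tests check over a 5-point sweep. Overlap
between clusters counts once; a cluster radius too large for the 0.5
point tolerance band raises an explicit "unreachable target" error.

**OEMRI phantom.** Per-pixel signal is
$S(t) = S_0\,(1 + a\,w(t)) + \varepsilon$, where $a$ is the pixel's true
enhancement amplitude and $w(t)$ is 0 during room air, rises as
$1 - e^{-t/\tau}$ during oxygen, and decays exponentially afterwards
(default $\tau$ = 5 frames against 30 frames per phase, so the enhanced
window sits within ~1.5% of the plateau). The amplitude field has a
configurable mean (default 0.22, i.e. +22% at steady state, a typical
healthy value), a linear cranial-caudal tilt, and — when CT ground truth
is supplied — a local reduction proportional to the emphysema fraction
at the matching cranial-caudal level. That coupling direction (emphysema
lowers oxygen enhancement) is physiologically motivated but its
functional form is a modeling choice of this generator, not an
established quantitative law. Noise is additive Gaussian, not Rician — a
documented simplification adequate at the simulated SNR (baseline 100,
noise SD 2); negative signals are clipped at zero with a reported count.

**Cohort.** Default 40 COPD and 9 control subjects. Imaging ground truth
is drawn per group (emphysema fraction 0.28 ± 0.10 vs 0.02 ± 0.01,
gradient 0.40 ± 0.20 vs 0.10 ± 0.05, MRER 12.6 ± 4.4% vs 22.0 ± 3.4%),
and clinical covariates follow linear links with Gaussian noise:
FEV~1~ and DL~CO~ decrease with the emphysema fraction, PaO~2~ decreases
with the gradient, SD-LAV and SD-RER increase with the gradient (SD-LAV
is deliberately the gradient's observable proxy, so that the
attribution structure — heterogeneity explains PaO~2~, severity explains
DL~CO~ — is recoverable by stepwise selection). Setting all noise SDs to
zero makes covariates equal their linear predictors exactly. With
`images = TRUE` the generator additionally produces a per-subject
CT/OEMRI phantom pair driven by the same ground truth and replaces the
noise-model imaging indices with measured ones; the demo pipeline uses
this mode at 8 + 3 subjects and 24³ volumes so a full end-to-end run
takes a few seconds.

What the phantoms do *not* emulate: airway trees, lobar fissures,
vasculature, scanner physics (beam hardening, reconstruction kernels),
respiratory motion, Rician noise, and the gravity dependence of
perfusion. Passing tests therefore demonstrate that the *measurement
chain* is correct and that the statistical layer recovers planted
structure — not that these indices behave identically on clinical scans.

## Numerical choices and degenerate inputs

- Remainder and tie rules (partition quotas to the earliest partitions,
  row-major in-slice order, coordinate ties broken by section) are fixed
  so every result is bit-reproducible; the demo pipeline re-run under
  one seed is byte-identical, and volumes are stored as uncompressed
  NIfTI so byte comparisons are meaningful.
- All randomness flows through one seeded generator per call
  (`withr::with_seed`); no global state is disturbed.
- Degenerate inputs fail fast with named errors: empty trachea mask,
  fewer than 12 lung-bearing slices, fewer pixels than partitions, empty
  phase windows, constant variables (reported as degenerate rather than
  tested), n too small for stepwise.
- A voxel exactly at the threshold is *not* low-attenuation (strict
  inequality); a pixel exactly at the baseline floor is kept.

## Known limitations

- The stepwise flavor (bidirectional, p-based) and its thresholds are
  one convention among several; selection frequencies quoted in the
  tests are properties of this convention on this generator.
- SD-LAV and SD-RER depend on partition count; 12-minus-2 and 10-direct
  are defaults, not universal standards.
- MRER pools pixels across sections; per-section averaging first would
  weight sections equally instead, and is available via the flags.
- The amplitude-emphysema coupling in the OEMRI phantom is qualitative;
  the package makes no claim about its clinical magnitude.
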