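---
title: "Quantifying air trapping from paired inspiratory/expiratory CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying air trapping from paired inspiratory/expiratory CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtrap)
```

## The problem

Small airway disease (SAD) — obstruction of airways under ~2 mm — is not
directly visible on CT and shows up in spirometry only after most of the
small airways are already compromised. Its indirect CT sign is *air
trapping*: lung regions that fail to empty on expiration and therefore
stay abnormally dark (low attenuation) on the expiratory scan. `airtrap`
quantifies air trapping from a paired inspiratory/expiratory chest CT
study, both with whole-lung densitometric summaries and with voxel-wise
maps on the co-registered pair, and provides the cohort-level statistics
used to evaluate such measurements against spirometry and case-control
labels.

## The measurement model

All attenuation is in Hounsfield units (HU; air ≈ -1000, water 0), and
volumes are clamped to the 12-bit CT range [-1024, 3071] on load. Two
fixed thresholds anchor every metric, following quantitative-CT
convention: voxels below **-950 HU on inspiration** indicate emphysema;
voxels below **-856 HU on expiration** indicate air trapping (fully
inflated normal alveoli average about -856 HU, and a proper exhale
raises parenchymal attenuation by roughly 150 HU).

Given lung masks for each phase, the conventional metrics are

* **MLA** — mean HU over the parenchyma, per phase;
* **E/I ratio** — `MLA_exp / MLA_insp` on raw (negative) HU, rising
  toward 1 with more trapping;
* **VDR** — `100 (V_insp - V_exp) / V_insp`, the percent lung-volume
  loss on exhale;
* **AVI** — `(MLA_exp - MLA_insp) / VDR`, the attenuation rise per
  percent of volume loss, which normalises the E/I idea for respiratory
  effort;
* **%LAA** — the fraction of mask voxels strictly below a threshold
  (-856 HU expiratory for trapping, -950 HU inspiratory for emphysema);
* **ND E/I** — the E/I ratio restricted to "seemingly normal" voxels
  (above -950 HU on inspiration *and* above -856 HU on expiration, taken
  jointly on the registered pair).

The voxel-wise maps require the expiratory scan expressed in the
inspiratory frame (Section "Registration"):

* **PRM** (parametric response map) classifies each joint-mask voxel by
  the two thresholds: *emphysema* (insp < -950, exp < -856), *fSAD* —
  functional small airway disease (insp ≥ -950, exp < -856), *normal*
  (both above), and the residual combination (insp < -950, exp ≥ -856)
  reported separately as *unclassified* so the four fractions sum to 1
  over the joint mask.
* **ATI** (air trapping index) takes the voxels "sufficiently inflated"
  on inspiration — HU in [-950, -856) — and calls a voxel trapped when
  its signed expiratory rise `exp - insp` is below 60 HU. ATI is the
  trapped fraction *of that band*, not of the whole lung; the two maps
  intentionally have different denominators.

Boundary handling: the threshold comparisons use strict `<` for "low
attenuation" and `>=` for "at or above", so a voxel exactly at -950 or
-856 counts as normal-side; the eligibility band is closed at -950 and
open at -856 to complement both strict rules. The ATI difference is
signed, so paradoxical density *drops* count as trapped.

## Segmentation

The package accepts externally produced parenchyma masks (the intended
clinical route; `load_mask()` checks the geometry against its CT). The
built-in fallback `segment_lungs_threshold()` thresholds at -320 HU,
removes air connected to the volume border, drops components below 1% of
the largest, and fills internal holes. It is adequate for phantoms and
clean studies; it does **not** exclude the trachea and main bronchi, a
known limitation for clinical use.

## Registration

The expiratory scan and mask are aligned to the inspiratory frame (the
default direction; the reverse is available via
`registration_config(direction = "exp_frame")`) by a 3-D affine
transform maximising Mattes-style mutual information: a 32-bin joint
histogram with linear Parzen windows, evaluated on up to 16000 positions
sampled inside the fixed lung mask. Four numerical choices matter and are
worth stating, because each addresses a concrete failure mode of masked
affine MI registration:

* **Interior sampling.** Sample positions are restricted to a 2-voxel
  erosion of the fixed mask. Samples at the lung edge interpolate across
  the lung/body boundary in the moving image; that penalty is minimal
  when the lung is mapped strictly inside itself, which biases the
  optimum toward over-contraction. Eroding the sampling mask removes the
  bias.
* **Jittered sampling.** Positions are voxel centres plus a uniform
  sub-voxel offset, and the fixed image is interpolated at them. Sampling
  exactly on the grid makes the metric dip at grid-aligned transforms
  (only fractional offsets average interpolation noise), which can pull
  the optimum up to a voxel away.
* **Smoothing at the finest level.** Coarser pyramid levels are smoothed
  implicitly by the block mean; the finest level gets a light Gaussian
  (sigma 0.7 voxel) before sampling. This lowers the voxel-noise floor of
  the metric — which otherwise scatters the optimum along the shallow
  scale/shear directions — while structure coarser than about two voxels
  survives.
* **Intensity ranges from the lung only.** The moving histogram range is
  taken from voxels inside the moving mask; including body and exterior
  air would stretch the 32 bins over ~3000 HU and make parenchymal
  structure invisible to the metric.
* **Capture before refinement.** At each level of a 3-level block-mean
  pyramid, the optimiser runs a translation-only simplex warm-up, a
  coarse sweep over uniform scale (exhale motion is scale-dominated),
  Nelder-Mead refinement of all 12 parameters, and a BFGS polish whose
  finite-difference steps are wide enough (0.25 on the optimiser scale)
  to step over voxel-scale metric wiggle. Because fine image texture does
  not survive 4x downsampling, the finest level additionally restarts the
  chain from the centre-of-mass initialisation and keeps whichever result
  ends at higher mutual information, followed by a fine per-axis scale
  sweep (the shallowest directions of the metric).

Everything is deterministic given the configuration's sampling seed.
Initialisation is centre-of-mass alignment of the two masks. Masks and
label maps are always resampled nearest-neighbour; the default for CT
intensities is also nearest-neighbour, which keeps HU values crisp so
that joint thresholding is not blurred across tissue edges — linear
interpolation mixes, say, a trapped voxel at -910 HU with a neighbouring
normal voxel at -740 HU into a value above the -856 HU threshold,
systematically eroding the trapped class. Linear interpolation is
available via `registration_config(interpolation = "linear")` for
applications that prefer smooth resampled intensities over crisp ones.

An affine model cannot express the regionally varying deformation of a
real exhale; it captures the bulk volume change and pose. No bending
energy or other regularisation is used because the bending energy of an
affine map is identically zero.

## The synthetic phantom

`make_paired_phantom()` generates paired studies with known composition:
a +40 HU body ellipsoid containing two lung ellipsoids in a -1000 HU air
box, on a 64 x 64 x 48 grid of 2.5 mm voxels by default (a half-scale
thorax that keeps a registration under a minute on one core). The lung is
partitioned into three tissue classes laid out from a disease focus in
the left lung outward — an emphysema core (5%, -980 HU inspiration,
rising 10 HU), an fSAD shell (20%, -920 HU, rising 10 HU), and normal
parenchyma (75%, -890 HU, rising 150 HU). Compact compartments are
deliberate: thin layouts put most class voxels on a boundary, where any
resampling mixes values across the class edge and distorts planted
fractions under motion. Class fractions are exact voxel counts
(largest-remainder apportionment), and the compartment boundaries are
frozen as continuous iso-distance surfaces so the expiratory phase can be
evaluated analytically at motion-transformed coordinates — the expiratory
volume is generated *in its own frame* and the pipeline must register it
back, the same path clinical data take.

Two stochastic/structural layers sit on top:

* **Noise** — independent Gaussian HU noise per voxel and phase (default
  sd 10), exercising threshold sensitivity.
* **Texture** — a smooth deterministic field (sum of sinusoids,
  amplitude 20 HU, wavelengths 9-43 mm) added to the lung in *both*
  phases at corresponding material points. It stands in for the vessels
  and septa that make real parenchyma registrable: constant compartments
  plus independent noise contain no inter-phase alignment signal, and
  affine MI recovery of a known motion would be ill-posed without it. Its
  amplitude is bounded so no class is ever pushed across a classification
  threshold, keeping the zero-noise oracles exact.

`truth` carries closed-form oracle values for every metric the pipeline
computes, derived from class counts, class means, exact per-class texture
sums and the motion determinant. At zero noise with identity motion the
pipeline must (and does, in the test suite) reproduce them exactly; after
registering the default exhale motion (uniform contraction to 88% linear
scale, about a 32% volume decrease ratio, plus a few mm of shift) under
default noise, class-fraction errors stay within 0.02 absolute.

What the phantom does *not* emulate: airway trees and lobes, gravity
gradients, scanner physics (beam hardening, dose, kernel), breathing-
level variability, and genuinely deformable motion. Passing phantom tests
therefore validates the pipeline's arithmetic, its registration under
affine motion, and its threshold logic — not clinical robustness to
anatomy and protocol variation.

## The cohort simulator

`simulate_cohort()` draws per-group multivariate-normal tables of QCT
metrics and percent-predicted spirometry, truncated to each variable's
domain by redrawing out-of-range entries (fractions to [0, 1], ratios and
spirometry to positive values; truncation biases extreme-fraction moments
slightly, which is acceptable for moment targeting at the defaults). The
default moments describe a case-control study of realistic scale — 46
patients with air-trapping fractions around 0.2-0.35 and depressed
spirometry against 27 controls — with a moderate within-group correlation
structure (air-trapping measures co-varying positively, tracking
spirometric obstruction negatively). Group means, SDs, sizes and the
correlation matrix are all settable, so tests can target specific
published moments and check recovery.

## Statistics

Standard procedures are delegated to base R (`cor.test`, `t.test` for
raw vectors, `glm` for the logistic model, `lm`, `p.adjust`); the layer
adds what those do not provide directly:

* summary-form Welch and pooled t comparisons, so a group comparison can
  be recomputed from a published table's (mean, sd, n) triplets — Welch
  is the default variant;
* Fisher r-to-z comparison of two independent correlations, plus the
  Williams-Steiger test for dependent correlations sharing a variable
  (the appropriate variant when two QCT metrics are compared on the same
  subjects against the same spirometric outcome);
* odds ratios per percentage point: fraction-valued predictors are
  multiplied by 100 by default, so an air-trapping OR reads "per 1% of
  lung volume";
* ROC analysis with the Mann-Whitney AUC (ties counted 1/2),
  Hanley-McNeil standard error, normal-approximation CI and p-value
  against AUC = 0.5, and a Youden-optimal cut-point (`J = sens + spec -
  1`, lowest threshold on ties, positivity rule `score >= c`). This
  estimator is implemented directly because each ingredient is part of
  the method's definition; the test suite cross-checks it against pROC
  and against exhaustive pair counting.

Missing values are handled by listwise deletion per analysis, with the
retained n reported. `bonferroni()` is `min(1, m p)` with `m` defaulting
to the number of tests.

## Problem sizes used in validation

The shipped tests and the acceptance script run on the defaults above:
64 x 64 x 48 phantoms (about 25,000 lung voxels) for end-to-end and
registration checks, 40 x 40 x 32 or smaller for arithmetic oracles,
cohorts of 46 + 27 for statistical checks, 10,000 null replicates for the
Pearson type-I-error calibration, and 2000 replicates for correlation
moment recovery. These sizes make every claim checkable in minutes on a
single core while keeping the phantom large enough that boundary effects
(a surface-to-volume phenomenon) stay well below the tolerances tested.

## Known limitations

* Affine-only registration; no deformable refinement.
* The fallback segmenter keeps the airway lumen attached to the lung if
  they connect below the threshold.
* DICOM support covers uncompressed little-endian 16-bit CT series (with
  RescaleSlope/Intercept); compressed transfer syntaxes and sequences are
  not parsed.
* The ND E/I selection is joint (one region on the registered pair); a
  per-scan variant is available via the `selection` argument since
  conventions differ between groups.
* `%LAA_exp < -856` is computed on the native expiratory scan and mask
  (registration-free, the conventional choice); `laa_on_registered =
  TRUE` switches it to the registered pair.
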