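---
title: "Methods: retinal oximetry and vessel tortuosity in oxytort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal oximetry and vessel tortuosity in oxytort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxytort)
```

## Overview

`oxytort` quantifies two properties of the retinal vasculature around the
optic nerve head (ONH) from dual-wavelength scanning-laser fundus images:
the oxygen content of individual arteries and veins, and the tortuosity of
their courses. Both are measured per vessel segment, aggregated per eye and
vessel type, and analyzed with linear mixed models across a two-group
cohort (normal controls, NC, versus sickle cell retinopathy, SCR). Because
clinical images of this kind are generally not shareable, the package
includes a forward model that renders synthetic image pairs with fully
known ground truth; every quantitative claim the test suite makes is
validated against that ground truth or against closed-form oracles.

## Vascular oxygen content

Imaging provides co-registered grayscale images at 532 nm (near-isosbestic
for hemoglobin, oxygenation-insensitive) and 633 nm (oxygenation-
sensitive). Vessels are detected on the 532 nm image with a multiscale
Frangi vesselness filter inside a circumpapillary annulus extending from 1
to 2 ONH radii. Along each vessel centerline, intensity profiles are
extracted perpendicular to the local tangent every 5 pixels; the vessel
boundary on each profile is the full width at half maximum (FWHM) of its
intensity dip, located by linear sub-pixel interpolation of the half-level
crossings.

Per wavelength, the optical density of a segment is the mean over profiles
of the ratio of the mean intensity *inside* the FWHM bounds to the mean
intensity *outside* (two flanking windows, each one vessel-width wide and
one vessel-width away from the edges). This inside/outside ratio is the
package default (`od_mode = "ratio"`); a conventional
`log10(outside/inside)` mode is available because the plain ratio inverts
the usual sense of an optical density. The optical density ratio
`ODR = OD633 / OD532` is converted to hemoglobin oxygen saturation by a
linear calibration

\[ SO_2 = a + b \cdot ODR, \]

clamped to [0, 100]%. The calibration coefficients are properties of the
instrument and hemoglobin spectra and must be supplied for real data; the
package defaults (`a = -150`, `b = 200`) are the synthetic forward model's
own calibration, chosen so that saturations from 0 to 100% map to ODR
values in [0.75, 1.25] and every render remains invertible. Oxygen content
follows as

\[ \mathrm{O_2\ content} = O_{2max} \cdot HgB \cdot SO_2 / 100
   \quad[\mathrm{mL\,O_2/dL}], \]

with `O2max = 1.34` mL O2 per g hemoglobin by default and the hemoglobin
concentration derived from hematocrit by the standard clinical rule
`HgB = HCT / 3` g/dL (both configurable).

## Vessel tortuosity

Tortuosity is measured on the 532 nm image in a larger annulus, 1.5 to 5
ONH radii, where vessel branches are more flexible. After Frangi
segmentation (excluding vessels narrower than 25 µm), the mask is thinned
to a one-pixel skeleton (Zhang–Suen), the skeleton graph is split at
branch points, and each branch-free path becomes one segment. Skeleton
chains carry up to half-pixel lattice jitter, so each chain is refined to
sub-pixel precision by snapping every point to the intensity valley along
the local normal (quadratic vertex fit around the deepest sample, followed
by a short running mean over the normal offsets). The refined chain is
smoothed by penalized cubic splines in `x(u)` and `y(u)`, `u` being arc
length normalized to [0, 1], with penalty weight `3e-5` on the integrated
squared second derivative; tangent angles and signed curvature come from
the spline derivatives, resampled at 1 px arc-length steps.

Per segment, the vessel tortuosity index is

\[ VTI = 0.1 \times SD_\theta \cdot N \cdot M \cdot L_A / L_C, \]

where `SDtheta` is the standard deviation (degrees) of the tangent angles
measured in the chord-aligned frame, `N` the number of critical points
(sign changes of dy/ds in that frame), `M` the mean arc/chord ratio over
the sub-segments delimited by inflection points and the endpoints, and
`LA`, `LC` the arc and chord lengths. The chord-aligned frame is the only
reading of "tangent angle relative to the x axis" consistent with the
index's rigid-motion invariance, which the package verifies to within
1e-6 relative (the smoothing splines are linear smoothers, hence exactly
rotation-equivariant). Every factor is dimensionless, so the index is also
scale-invariant. A straight segment has `N = 0` and therefore `VTI = 0`
exactly. The alternative reading of `SDtheta` as the standard deviation of
*consecutive* tangent-angle differences is exposed as
`compute_vti(sd_mode = "differences")` without being the default.

The vessel inflection index (VII) is the number of sign changes of the
signed curvature along the centerline. A `k`-period sinusoid has exactly
`2k - 1` interior curvature zeros, which the test suite uses as analytic
ground truth, both on sampled curves and on rendered images.

### Numerical tolerances

Zero-crossing counts on measured data need explicit zero bands. On
analytic centerlines the spline reproduces straight lines to |kappa| ~
1e-13, and the primitive defaults (`kappa_eps = 1e-6` per px,
2-sample endpoint buffer, `crit_eps = 1e-6` on dy/ds) suffice. On rendered
images the sub-pixel refinement leaves a measured curvature noise floor of
at most ~2e-3 per px on straight vessels, while the gentlest real
undulations in the synthetic cohort have curvature above 1.3e-2 per px;
the image-level defaults are therefore `kappa_eps = 4e-3` (2x above noise,
3x below signal) and `crit_eps = 0.01` on the dimensionless chord-frame
slope. Both are configuration fields, not hard-coded constants. For
profile geometry in oximetry, the centerline spline uses a stiffer penalty
(0.01) than the tortuosity spline: profile extraction needs stable
tangents, and the short chains of the inner annulus would otherwise
inherit pixel-level jitter as oblique profiles and widened FWHM estimates.

## The synthetic forward model

`render_pair()` draws each vessel as an inverted Gaussian cross-profile
whose FWHM equals the nominal caliber. The dip depth is pre-compensated by
the factor \(\sqrt{\pi}\,\mathrm{erf}(\sqrt{\ln 2})/(2\sqrt{\ln 2})
\approx 0.810\) — the mean of a Gaussian over its own FWHM window — so
that the *FWHM-window mean* transmittance equals the target optical
density: `od532_base` at 532 nm and `od532_base * ODR(so2_true)` at
633 nm. With that convention the oximetry chain is exactly invertible in
the noiseless limit; the acceptance suite requires SO2 recovery within 2
percentage points and caliber within 10% for vessels of at least 25 µm.
The ONH is rendered as a bright disc whose center and radius are written
to a JSON annotation (the ONH is treated as given, never detected); before
vesselness filtering the disc is replaced by the median of its surrounding
band so its step edge cannot masquerade as a vessel. Images are stored as
16-bit grayscale TIFF, one file per wavelength.

`generate_cohort()` defines the simulated study conditions. Defaults,
chosen once: 12 + 12 subjects, two eyes each, 4 arteries and 4 veins per
eye plus one 15 µm capillary (to exercise the caliber filter); arterial
SO2 centered at 92%, venous at 58%; SCR subjects receive a 3-point SO2
deficit and a +2 shift in per-vessel inflection counts (NC counts center
near 8); hematocrit 42 ± 3% (NC) versus 28 ± 4% (SCR, reflecting
sickle-cell anemia); ages 46 ± 4 versus 41 ± 15 years; blood pressures
giving mean arterial pressure (`MAP = (SBP + 2 DBP)/3`) centered near 93
versus 82 mmHg. Oxygen content is linked to the inflection count with
slope -0.5 mL O2/dL per inflection, on top of a subject-level random
intercept (SD 1.5) and per-segment noise (SD 1.2), so the O2-versus-VII
regression has a known true coefficient. These settings give arterial
oxygen content near 17 (NC) versus 11 (SCR) and venous near 11 versus 7
mL O2/dL.

Two output modes share this construction. With `render = FALSE` the
generator emits per-segment measurement tables directly (ground truth plus
the configured noise), which is what the statistical recovery simulations
use: regenerating and re-analyzing dozens of image pairs per seed would
add nothing to a test of the mixed model. With `render = TRUE` each eye
becomes an image pair carrying the same ground truth, feeding the
image-analysis round trips and the end-to-end pipeline.

What the generator does *not* emulate: retinal texture, vessel branching
trees and crossings, eye-motion and chromatic mis-registration artifacts,
pathology-specific absorption spectra (sickle hemoglobin differs from the
adult hemoglobin the linear calibration assumes), and clinically scaled
undulation amplitudes — rendered vessels undulate at amplitudes of a few
pixels so inflections are resolvable at the 10 µm/px scale, which makes
their VTI values larger than clinical ones (the table-mode generator
draws VTI at the clinical scale, near 0.16). Passing tests therefore
demonstrate correctness of the measurement chain on idealized vessels, not
robustness to every property of real fundus images.

## Cohort statistics

Per-segment records are averaged per subject x eye x vessel type. Rows
whose `o2_content`, `vti` or `vii` fall outside mean ± 3 SD of their
diagnosis x vessel-type stratum are removed (strata with fewer than 5 rows
are left untouched); the criterion is this package's construction — the
removal of outliers in such analyses is standard but rarely specified —
and both the band and the log of removals are exposed.

Group comparisons use linear mixed models fit by REML with a subject
random intercept, which is how fellow-eye correlation is controlled when
both eyes contribute rows: `response ~ diagnosis + eye + vessel_type +
age + map + (1 | subject_id)` for each of O2 content, VTI and VII, and
`o2_content ~ metric + vessel_type + eye + age + map + (1 | subject_id)`
for the O2-tortuosity association. Inference uses t statistics with
Satterthwaite degrees of freedom (via lmerTest); at these sample sizes a
plain Wald-normal approximation would be anti-conservative. Singular
random-effect fits fall back to maximum likelihood with a flag and a
warning. Parameter recovery is verified by simulation: across 20 seeds of
the default cohort, the 95% interval for the O2-vs-VII coefficient covers
the true -0.5 in at least 18, and with a zero imposed slope the term is
non-significant in at least 90% of seeds.

Shannon entropy and mutual information summarize the information content
of the two tortuosity metrics over the cohort rows. Values are binned into
equal-width histograms over the data range with `ceiling(sqrt(n))` bins by
default, and logs are base 2; both choices are this package's
construction, as no standard binning exists for these quantities, and both
are arguments. Entropy of a degenerate sample is 0; mutual information of
an exactly factorized joint table is 0 and `MI(x, x) = H(x)`;
`0 <= MI <= min(H(x), H(y))` holds up to rounding.

## Problem sizes and determinism

The shipped configuration renders 320 x 320 px eyes with a 30 px ONH
radius at 10 µm/px: large enough that the 1.5-5 radius annulus fits with
margin and a 25 µm vessel spans 2.5 px, small enough that a full
simulate-measure-model cycle for a 2 + 2-subject cohort completes in under
a minute. Statistical simulations use the full 12 + 12 design in table
mode. All randomness flows from a single integer seed: renders are
bit-identical, and `run_all()` reproduces every CSV/JSON output
byte-for-byte under a fixed configuration, which the acceptance suite
checks with file hashes.

## Known limitations

- The SO2 calibration is linear over the working ODR range; saturations
  implying an ODR outside the invertible range of the render are rejected
  rather than extrapolated.
- Vessel segments are analyzed independently; no reconnection across the
  ONH or across branch points is attempted, so one anatomical vessel may
  contribute several segments.
- The FWHM boundary detector assumes a single dominant intensity dip per
  profile; profiles contaminated by a neighboring vessel are skipped
  rather than deblended.
- Artery/vein identity is taken from ground truth (or user annotation),
  not estimated from the images.
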