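---
title: "Quantifying intra-Golgi transport with GLIMtools"
author: "GLIMtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-Golgi transport with GLIMtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GLIMtools)
```

## The measurement model

A nocodazole-induced Golgi ministack is imaged in three channels: the cis
marker GM130, the trans marker GalT-mCherry, and a cargo. Each channel's
signal is a diffraction-limited punctum; its sub-pixel position is the
intensity-weighted center of mass of background-subtracted pixels. With
displacement vectors $a = \mathrm{cargo} - \mathrm{GM130}$ and
$b = \mathrm{GalT} - \mathrm{GM130}$, the localization quotient is the
signed axis projection

$$LQ = \frac{a \cdot b}{b \cdot b}.$$

We use the projection form deliberately: the phrase "ratio of axial
distances" only determines $LQ$ up to sign, and the projection is the one
reading under which positions before the cis face (ERES/ERGIC, $LQ <
-0.25$) and beyond the trans face ($LQ > 1$, TGN) are meaningful, and
under which a lateral (perpendicular) displacement of the cargo leaves
$LQ$ unchanged. GM130 maps to exactly 0 and GalT-mCherry to exactly 1 by
construction, and one LQ unit corresponds to 274 nm of axial distance
(`NM_PER_LQ`), a calibration obtained by side averaging.

Chase-synchronized cargos (RUSH) follow first-order kinetics

$$LQ(t) = y_0 - A\,e^{-\ln 2\, t/t_{intra}},$$

with $y_0$ the exit-site LQ and $t_{intra}$ the half-range time. The
instantaneous velocity follows either as a function of time,
$\frac{dLQ}{dt} = \frac{A \ln 2}{t_{intra}} e^{-\ln2\,t/t_{intra}}$, or —
eliminating $t$ — as a function of position,
$\frac{dLQ}{dt} = \frac{\ln 2}{t_{intra}} (y_0 - LQ)$. The two
parameterizations agree identically (tested to $10^{-12}$); the positional
form is what lets velocities of different cargos be compared *within the
same cisterna*, conventionally at the medial position $LQ = 0.40$.

## Processing pipeline and its parameters

**ROI detection** (`detectROIs`) finds local maxima of a Gaussian-smoothed
(σ = 2 px) sum-of-channels image above median + 8 MAD — a robust floor
that admits nothing in a blank field — and assigns each a fixed square box.
The half-width default of 11 px (≈ 715 nm at 65 nm pixels) covers half the
300 nm stack axis plus 4 PSF sigmas, which keeps Gaussian-tail truncation
of off-centre spots below $10^{-4}$ LQ units in noiseless round trips.
Overlapping boxes are discarded *pairwise* (both members): the conservative
tie-break, since a crowded pair contaminates each other's centroids.

**Background** is the median of the one-pixel border ring of each ROI,
subtracted with negatives clamped at zero. This is a deliberately simple,
assumption-free estimator; optimization- or learning-based background
extraction is out of scope.

**Chromatic correction** (`fitChromaticModel`) uses a multi-colour bead
field: beads detected on the reference channel, per-channel centroids
measured in a *tight* window (radius 6 px ≈ 2.5 σ) that is iteratively
re-centred on each channel's own spot. The tight window matters: centroid
variance from background shot noise grows with the squared window radius,
and re-centring removes the asymmetric-truncation bias that a window
centred on the reference position would impose on a shifted channel. The
default transform is a per-channel translation — sufficient for the
sub-pixel shifts typical between filter cubes — with a full affine model
behind a flag for optics with measurable magnification differences.

**QC gates** (`filterAnalyzable`): the cis-to-trans axis must measure
70–1000 nm and all three channels must have positive integrated intensity.
The bounds are configurable stand-ins: the lower bound must exceed the
localization error (tens of nm), the upper bound plausible stack size;
the published analyzability criteria live in prior methodological work and
are not restated here.

## Kinetic fitting choices

`fitIntraGolgiKinetics` uses Levenberg–Marquardt least squares with the
initialization $y_0 \leftarrow$ last observed LQ, $A \leftarrow y_0 -$
first observed LQ, $t_{intra} \leftarrow$ the time nearest half-range,
refined over a 5-point multiplicative multi-start grid
(0.25–4 × the initial $t_{intra}$); the best converged start by deviance
wins, and an error lists the starts tried if none converges. Fits are
unweighted by default — matching the common default of the interactive
fitting tools used for such data — with $1/\mathrm{SEM}^2$ weighting
behind a flag, since the original weighting is not documented. Adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$ with $p = 3$; published fits of this
kind reach adj. $R^2 \ge 0.85$. Early chase points ($t \le 5$ min) carry
a high ER background in practice; a `tMinExclude` option can drop them,
but the default uses all points.

Replicate summaries print as mean ± SD with the sample SD (n − 1) rounded
half-up to one significant figure and the mean to the same decimal place
("8±1", "14.2±0.6"). Half-up rounding (`roundHalfUp`) is used everywhere
printed values are regenerated, since fixed-precision tables conventionally
round ties away from zero, not half-even.

## Golgi residence times

Decay traces fit $y = y_0 + A_1 e^{-x/t_1}$; the residence time is
$t_{1/2} = 0.693\,t_1$, using the conventional constant 0.693 rather than
$\ln 2$ at full precision (difference < 0.03%) so regenerated values match
published tables digit for digit — e.g. a 204 min mean prints as "3.4 h".
A fit is accepted only if adj. $R^2 \ge 0.80$ and the acquisition spans at
least $1.33\,t_{1/2}$, the half-time test being made against the *fitted*
$t_{1/2}$ (the only self-consistent reading of the rule). Time-lapse
segmentation thresholds the smoothed Golgi-marker channel per frame with
Otsu's method — no specific method being prescribed, an automatic
parameter-free threshold was chosen — and integrates the reporter inside
the mask after border-ring background subtraction. Intensities are raw
integrated values; whole-cell normalization is not applied (whether the
original workflow normalized is not documented).

## Side and en-face averaging

Side views are identified by giantin double puncta. Each image is
registered in a single bilinear resampling pass: rotated so the punctum
axis is horizontal, rescaled so the punctum separation matches the median
separation across the stack (scale normalization without an absolute
standard), and aligned on the punctum midpoint; the order
rotate → rescale → normalize → average is adopted. Which end of the
axis is cis is not a convention we inherit, so it is resolved per image:
if the cis marker's center of mass lands below the trans marker's after
rotation, the image is flipped vertically. Channels are max-normalized
before averaging. Axial centers of mass are computed on
support-restricted images (pixels below median + 3 MAD zeroed) so the
uniform camera background cannot drag the center of mass toward the image
centre; the truncation is symmetric about a band and leaves its centre
unbiased. Axial line profiles (lateral sums) are fitted with a single
Gaussian *plus a constant baseline* — the baseline term absorbs the
residual background, and marker distances are differences of fitted
centres $Xc$. En-face views (giantin rings) are translated to centre,
rescaled to the median ring radius, normalized and averaged; radial mean
intensity profiles use one-pixel annuli with the radius normalized to the
ring radius.

## The synthetic generator: what it emulates, and what not

`simulateMinistackField` renders each ministack as three isotropic 2D
Gaussian spots (the projected PSF of sub-resolution objects): GM130 at the
anchor, GalT at 300 nm along a random (or fixed) axis direction — the
measured pre-perturbation GM130-to-GalT spacing — and the cargo at
`cargoLqTrue` × 300 nm, with optional perpendicular offset. Pixel sizes
follow the instruments emulated: 65 nm (wide-field), 89 nm (spinning
disk), 45 nm (Airyscan side views, the side-view default). Noise follows
the standard camera model — Poisson on signal plus background, then
additive Gaussian read noise. No intensity statistics for real ministack
puncta are published, so the photon budget is a free parameter chosen once
at a realistic value for bright transfected puncta at sub-second-to-second
exposures: 5000 expected photons per spot over a 20 photon/px background
with 2-count read noise, giving peak SNR ≈ 30. Coordinates are 0-based
pixels; physical nm from the top-left pixel centre; axis angles
counter-clockwise from +x. Identical configuration and seed give
bit-identical arrays, and the generators restore the caller's RNG state.

What the simulations do *not* model: 3D PSFs and defocus, realistic Golgi
ribbon morphology, cisternal substructure, chromatic aberrations beyond a
per-channel affine transform, drift, or drug-induced reorganization
dynamics. Passing round trips therefore demonstrate the correctness of the
measurement chain — localization, correction, projection, fitting,
registration — not robustness to every property of real micrographs.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to give stable statistics
at desk scale: noiseless round trips on 8-stack fields (LQ error
< $10^{-3}$); a noisy-bias check pooling 7 fields × 25 stacks (≥ 100
analyzable ministacks, bias within 2 SEM); 200 seeded kinetic simulations
at the generator defaults (median relative $t_{intra}$ error < 10%);
200 seeded decay recoveries (|bias| < 5%); 20-image side averages
(marker distance 300 ± 10 nm); 25-bead chromatic fields (shift error
< 0.05 px). Degenerate inputs fail softly where the assay does (zero
intensity and zero-length axes are QC failures; coincident puncta and
zero-radius rings are skipped and counted) and hard where the input is
malformed (empty time grids, non-increasing times, missing channels,
unknown config keys).

Published per-replicate fit parameters ship in
`inst/extdata/rush_reporter_kinetics.csv`. One replicate (SBP-GFP-CD59 #1,
293T) is recorded with $t_{intra} = 0.74$ min: that value — not the 0.4
that a corrupted rendering of the table suggests — reproduces the row's
own printed velocity columns (0.244 LQ/min, 66.7 nm/min) and its group
summary, and is kept as printed-value-consistent. For three cells of the
velocity columns (E-cadherin #2 and #3, furin-YA #1) the printed
velocities were evidently computed from unrounded fit parameters: no value
at the printed input precision regenerates them exactly, and the
regeneration tests document the one-final-digit differences rather than
adjusting the inputs.

## Known limitations

Localization is 2D; axial (z) structure is projected. The LQ is a
centre-of-mass statistic: multimodal cargo distributions (e.g. a cargo
split between two cisternae) yield an average position. Side averaging
assumes approximate rotational symmetry of ministacks and sufficient
puncta annotation accuracy; its scale normalization is relative, so only
the 274 nm/LQ calibration anchors absolute distances. The residence-time
model assumes a single exponential pool; two-pool decays will fail the
adj. $R^2$ gate rather than fit.
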