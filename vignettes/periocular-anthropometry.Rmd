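---
title: "Automated periocular anthropometry: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated periocular anthropometry: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periometry)
```

## The measurement problem

Oculoplastic assessment relies on a small set of periocular distances:
the marginal reflex distances MRD1 and MRD2 (vertical distance from the
pupillary centre to the upper and lower eyelid margin), the palpebral
fissure height PFH = MRD1 + MRD2, the horizontal palpebral aperture (HPA),
and the inner/outer intercanthal and interpupillary distances (IICD, OICD,
IPD). Manual rulers and penlights are subjective and operator-dependent;
this package automates the full chain on frontal photographs:

1. **Landmark detection.** Ten periocular landmarks — per eye: pupillary
   centre, upper and lower lid-margin midpoints, medial and lateral canthus
   — are predicted by a convolutional network trained with Gaussian heatmap
   regression.
2. **Calibration.** A green adhesive dot of known diameter (24 mm by
   default) worn on the forehead converts pixels to millimetres.
3. **Measurement.** The seven metrics are computed from the calibrated
   landmark geometry.
4. **Agreement.** Automated measurements are compared against a human
   rater with MAE, Bland–Altman limits of agreement, and ICC(A,1).

Because no clinical photograph set is distributed with the package, every
component is validated on a synthetic scene generator whose ground truth is
analytic.

## Heatmap regression

For landmark $l$ at position $(x_l, y_l)$ the training target at heatmap
cell $(u, v)$ is

$$H^*_l(u,v) = \exp\!\left(-\frac{(u-\tilde x_l)^2 + (v-\tilde y_l)^2}{2\sigma^2}\right),$$

where $(\tilde x_l, \tilde y_l)$ is the landmark quantized to the heatmap
grid at $1/4$ of the input resolution. We fix $\sigma = 2$ heatmap pixels,
truncate the Gaussian beyond $3\sigma$, and normalise the peak to 1 rather
than to unit mass — the standard choices in heatmap-based keypoint work,
where only the argmax neighbourhood matters. The loss is the mean squared
difference between predicted and target stacks; using the *mean* (not the
sum) makes the magnitude independent of input size and batch composition.

Decoding takes the argmax cell of each predicted map (ties resolved by
row-major first occurrence), shifts a quarter cell toward the larger of
each axis pair of 4-neighbours, and multiplies by the stride. The
quarter-offset refinement halves the expected quantisation error and is
exactly testable: the encode→decode round trip is bounded by the stride
(4 px) in the $L_\infty$ norm, and averages well under 2 px.

All coordinates in the package are 0-based with the origin at the centre
of the top-left pixel, x rightward, y downward; annotations, heatmap
arithmetic and measurements share this convention.

## The compact backbone

The detector backbone is pluggable (`register_backbone()`); the built-in
`"compact"` network is a small encoder–decoder: three stride-2 3×3
convolutions (to 1/8 resolution), one 3×3 convolution at 1/8, nearest
up-sampling to 1/4 with an additive skip from the second stage, and a 1×1
head emitting ten maps. Two design points matter:

* **Coordinate channels.** The input is luminance plus two normalised
  coordinate maps. Several landmark roles are locally ambiguous — a
  medial canthus of the right eye is a near-mirror of its left twin —
  and a small-receptive-field network cannot see across the face to
  disambiguate them. The coordinate channels restore that positional
  information at negligible cost.
* **CPU-scale capacity.** The default channel widths (8/16/24, scaled by
  the `width` multiplier) train in minutes on one CPU core. This is a
  deliberate trade: the pipeline around the detector, not a specific
  large architecture, is what the package exercises and validates. An
  HRNet-class backbone can be registered where GPU capacity exists.

Training follows the photographic protocol defaults: Adam, batch 16,
60 epochs, base learning rate $10^{-3}$ decaying to $10^{-4}$ at epoch 30
and $10^{-5}$ at epoch 50, augmentation by in-plane rotation (±30°),
isotropic scaling (0.75–1.25) and horizontal flips (p = 0.5), and a 70/30
train/evaluation split drawn deterministically from the configured seed.
A horizontal flip swaps the right-eye landmark block with the left-eye
block so each role keeps its anatomical meaning; an augmentation draw that
pushes any landmark out of frame is re-drawn up to five times and then
abandoned (the sample passes through unaugmented, and the count is kept on
the model object).

Accuracy is summarised by the normalised mean error — the mean Euclidean
landmark error divided by the ground-truth inter-pupillary pixel distance
— and the failure rate, the fraction of images with NME above 0.1. The
inter-pupillary normaliser is a convention choice (the field also uses
inter-ocular distances); it is the natural scale-free reference available
in every face.

## Synthetic scenes as ground truth

`render_scene()` draws a schematic face fragment: two eyes built from
parabolic lid arcs through the canthi and lid midpoints, an iris and pupil
disc clipped to the aperture, dark lid-margin lines, and the green
fiducial disc, on a skin-toned background with Gaussian pixel noise.
Landmarks are computed from the geometry *before* rasterisation — the
raster is only the network input — then the whole scene (raster and
coordinates together) is rotated by the head-roll angle, so vertical MRD
measurements on rolled scenes genuinely exercise the coordinate
convention.

The generator's population defaults mirror adult clinic values: MRD1
3.66 (0.89) mm, MRD2 5.24 (1.22) mm, HPA 25.30 (2.08) mm, IPD 61.2 (3.7)
mm, IICD 33.3 (3.4) mm, each drawn from a normal truncated at ±2 SD
(bilateral metrics independently per side). OICD is *derived* as
IICD + HPA$_R$ + HPA$_L$ — the horizontal layout identity makes it
dependent, and the implied mean (83.9 mm) matches the measured population
(83.7 mm) closely. The scale is drawn uniformly from 0.21–0.25 mm/px
(camera standoff variation), head roll from a ±5°-truncated normal with
SD 2°, and pixel noise SD 0.02 on unit-scaled intensities. These defaults
are fixed study conditions, not tuning knobs.

What the scenes do **not** emulate: eyelashes, brows, skin texture,
specular corneal reflexes, occlusion, out-of-plane pose, lighting
gradients, and lens distortion. Passing synthetic validation therefore
demonstrates that the pipeline's geometry, calibration arithmetic,
training loop and statistics are correct — not that the compact detector
generalises to clinical photographs. Clinical use requires retraining on
annotated photographs through exactly the same interfaces.

## Calibration

`detect_sticker()` thresholds green pixels (green channel dominant by a
configurable margin), labels connected components, and keeps candidates
with area ≥ 50 px and circularity $4\pi A/P^2 \ge 0.8$. The perimeter $P$
uses the Cauchy–Crofton corrected estimate $P = (\pi/4)\,E$, where $E$
counts in/out 4-neighbour edge crossings: a raw boundary-pixel count
systematically overestimates the perimeter of a rasterised disc (staircase
effect) enough to fail the 0.8 gate, while the corrected estimator scores
an ideal disc at ≈ 1. The largest qualifying component wins; a
least-squares (Kåsa) circle fit to its boundary pixels gives the radius,
and mm/px = diameter / (2·radius). A fit whose RMS boundary residual
exceeds 10% of the radius is flagged as degraded. The calibration assumes
the sticker and the eyes are coplanar at the camera standoff; parallax is
ignored, as it is in the photographic protocol itself.

## Measurement conventions

MRD1 and MRD2 are *signed vertical* (y-axis) components, not Euclidean
distances: the definition is "vertical distance", the lid midpoints sit on
the pupil's vertical line, and a lid at or below the pupil centre (severe
ptosis) is meaningfully negative. PFH = MRD1 + MRD2 holds bit-exactly by
construction. The horizontal metrics (IPD, IICD, OICD, HPA) use full
Euclidean distances, which makes them invariant to small head roll; with
a level head they coincide with the x-components (a switch is provided).
Reported tables round to 2 decimal places in mm.

## Agreement statistics

With paired values $(A_i, B_i)$ and $d_i = A_i - B_i$:

* **MAE** $= \operatorname{mean}|d_i|$, with the sample SD of $|d_i|$.
* **Bland–Altman**: bias $\bar d$, limits of agreement
  $\bar d \pm 1.96 s_d$, CI of the bias $\bar d \pm t_{n-1} s_d/\sqrt n$,
  and CI of each limit using the $s_d\sqrt{3/n}$ standard-error
  approximation. The 1.96 multiplier and the $\sqrt{3/n}$ term are the
  conventional forms.
* **ICC(A,1)** (single measures, absolute agreement, two-way):
  $\mathrm{ICC} = (MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$
  from the subjects × raters ANOVA mean squares, with the McGraw–Wong
  F-based confidence interval, and a p-value for $H_0{:}\ \mathrm{ICC}=0$
  from $F = MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of freedom.
  Reliability bands: poor < 0.5 ≤ moderate < 0.75 ≤ good ≤ 0.9 <
  excellent.

Bilateral metrics pool left and right eyes (two pairs per face), central
metrics contribute one pair per face; the pooled pairs are treated as
independent, replicating common practice even though eyes within a face
are correlated — a per-face analysis can be run by passing single-side
records.

Degenerate inputs are handled explicitly: zero difference variance
collapses the limits of agreement onto the bias with zero-width intervals;
zero between-subject variance makes the ICC undefined and raises an error
rather than returning a misleading number.

## Problem sizes and validation

The test-suite and the reproduction script run everything at CPU desk
scale, which the package adopts as its own validated configuration:
scenes at 512 × 256 px, detector input 256 × 128 (anisotropic stretch with
the affine recorded for inverse mapping), width-1.5 compact backbone,
30 epochs with milestones at 21 and 28. On 200 training and 60 held-out
scenes this configuration reaches a held-out mean NME of about 0.03 and a
failure rate at 0.1 of 0 across training seeds, and trains in a few
minutes on one core. Statistical routines are validated against
independent oracles (an `aov()`-based variance-components computation for
the ICC; brute-force loops for MAE and NME), the Bland–Altman limits
against Monte-Carlo coverage, and the geometry against
generator↔measurement round trips.

## Known limitations

* The compact backbone is intentionally small; clinical deployment needs
  a stronger backbone and real annotated photographs.
* MRD is defined in the image frame: large head roll biases it downward
  by the cosine of the roll (0.4% at 5°). The generator keeps roll small;
  real pipelines should correct pose first.
* Calibration ignores sticker-to-eye parallax and lens distortion.
* Synthetic scenes are schematic; see the generator section for the list
  of unmodelled photographic effects.
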