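---
title: "Quantifying widefield OCTA scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying widefield OCTA scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octarepeat)
```

octarepeat implements a complete post-processing and repeatability-analysis
pipeline for widefield swept-source OCT angiography (OCTA). A widefield
acquisition produces en-face angiograms of three depth slabs — the
superficial capillary plexus (SCP), the deep capillary plexus (DCP) and the
choriocapillaris (CC) — on a 15 x 9 mm field sampled at 800 x 534 pixels,
i.e. a pixel pitch of (18.75, 16.854) micrometres. The pipeline derives,
for each eye and visit:

1. the perfusion density (PD) of the **large retinal vessels**, segmented
   from the SCP by a combined Gabor and Hessian enhancement with a
   mean-derived threshold;
2. the PD of the **SCP and DCP** under each of four enhancement variants
   (no filter, Hessian vesselness, Gabor bank, Bayesian residual
   shrinkage), binarized by local adaptive thresholding;
3. **choriocapillaris flow-void** area, count and mean size at
   standard-deviation threshold multipliers of 1 and 1.25, with large
   vessels and the optic disc excluded;

each reported for a fovea-centred 6 x 6 mm macular square and its
peripheral complement, and finally summarized across two visits per subject
with paired t-tests, two-way random-effects intraclass correlation
coefficients, Bland–Altman limits of agreement, and Pearson correlations of
each filtered variant against the unfiltered reference.

Because clinical scans of this protocol are not freely available, the
package carries a first-class synthetic-scene generator with exact ground
truth, which the tests and the acceptance script use to validate every
stage end to end.

## Image model and conventions

An `angiogram` is a numeric matrix of intensities normalized to [0, 1]
with an explicit per-axis pitch in micrometres. Rows are the y (slow) axis,
columns the x (fast) axis; all pixel coordinates are 0-based `(row, col)`
pairs and a pixel is identified with its centre. Pitch is never read from
image headers — it comes from the cohort manifest — because exported
en-face images rarely carry trustworthy physical metadata.

One wrinkle worth stating: a 15 x 9 mm field on an 800 x 534 grid is
described by the vendor as isotropically sampled, but 15000/800 = 18.75
and 9000/534 = 16.854 micrometres differ by 10%. The package treats the two
pitches as independent quantities everywhere (kernels, windows and region
sizes are converted per axis), and both are configurable.

All filters use reflect padding: widefield frames often end in a dark rim,
and circular or zero padding would manufacture spurious ridge responses at
the boundary that inflate peripheral measurements.

## Vessel enhancement filters

**Hessian (Frangi) vesselness.** Vessel diameters between 15 and 44 µm
(capillary to small-arteriole calibre) are covered by `n_scales = 4`
log-spaced scales. A diameter d maps to a Gaussian scale sigma = d/4 per
axis — a Gaussian ridge of width d produces its strongest second-derivative
response near that sigma. At each scale the scale-normalized Hessian
(gamma = 2) is assembled from separable Gaussian-derivative convolutions,
its eigenvalues ordered by magnitude, and bright ridges (lambda2 < 0)
scored by the Frangi vesselness with beta = 0.5 and the structureness
constant c set to half the per-scale maximum Frobenius norm. The output is
the maximum over scales, which lies in [0, 1] by construction. The source
protocol names only the filter family and the size range; Frangi's
formulation is the citation-consistent default in this literature, and
beta, c and the diameter-to-sigma rule are all exposed.

**Gabor bank.** Sixteen even-symmetric, zero-mean Gabor kernels spaced
pi/16 apart span [0, pi); the per-pixel maximum of the sixteen responses is
min-max rescaled to [0, 1]. The published wavelength of "20 pi" carries no
unit; we interpret it as pixels (about 62.8 px), which is the only reading
that keeps the number dimensionless in the original MATLAB context, and we
expose it as a parameter. Envelope width follows sigma = 0.56 x wavelength
with aspect ratio 0.5, common defaults for vessel enhancement. The
orientation label denotes the stripe (vessel) direction: the theta = 0
kernel responds maximally to a horizontal bar. Whether the published
pipeline took the max or the sum over orientations is unstated; max is
standard for vessel enhancement and is what we implement.

**Bayesian residual shrinkage.** The image is decomposed into `n_levels =
4` residual layers by iterated Gaussian smoothing (sigma doubling from 1
px), each layer shrunk by the minimum-MSE rule under a Gaussian noise
model — soft thresholding at T = sigma_n^2 / sigma_s with sigma_s^2 =
max(var(layer) - sigma_n^2, 0), the BayesShrink threshold — and the image
reconstructed by summation and clipped to [0, 1]. The noise SD is estimated
from the finest residual by the robust rule median(|r|)/0.6745 unless
given. The underlying publication specifies the filter only by citation;
this residual-pyramid scheme is our concrete, testable realization, and
`noise_sd_estimate = 0` reduces it to the identity exactly, which the tests
assert.

## Binarization and perfusion density

Local adaptive binarization marks a pixel as vessel iff its intensity
strictly exceeds the local mean over a 1.25 mm square window (67 px along
x, 75 px along y at default pitch; nearest odd integer per axis) plus an
offset (default 0). The strictly-greater tie rule sends constant regions to
background; since the local mean is computed by FFT convolution, an epsilon
of 1e-8 guards the comparison so the rule is exact under floating-point
roundoff. With offset 0 the rule is invariant to positive affine intensity
maps, so PD does not depend on display scaling — a property the tests
check. PD is simply 100 x (vessel pixels in region) / (region pixels),
with optional exclusion masks removed from both numerator and denominator.

Large vessels are segmented from the SCP by the elementwise maximum of a
Gabor response and a Hessian response restricted to the 30–44 µm band,
thresholded at 2 x the mean of the enhanced image, with components under
50 px discarded as capillary speckle. Two open constants live here: the
published "derived threshold from the mean intensity" gives no factor (we
default to 2, exposed), and the Gabor kernel for this stage is not
parameterized in the protocol. The plexus-enhancement default of 62.8 px
would be far coarser than large-vessel calibre (2–6 px at default pitch)
and smears the mask; we match the wavelength to vessel calibre (4 px, unit
aspect), which recovers the generator's vessel tree with Dice 0.84–0.88
across independent scenes. The SCP-derived mask is computed once per eye
and reused for the DCP and for choriocapillaris exclusion, following the
flowchart ordering of the original processing chain.

## Regions

The macula is the axis-aligned 6 x 6 mm square centred on the fovea
(default: the geometric image centre, since the scan protocol is
fovea-centred; overridable per image in the manifest). A pixel belongs to
the macula iff its centre lies in the half-open rectangle [centre - 3 mm,
centre + 3 mm) on each axis — half-open so that macula and periphery
partition the grid exactly, with no border pixel counted twice. At default
pitch this yields exactly 320 x 356 macular pixels. The optic disc is
excluded only from the choriocapillaris analysis (the protocol states disc
masking only there); whether the original work also excluded it from
peripheral retinal PD is not recoverable, so retinal PD uses no exclusions
by default.

## Choriocapillaris flow voids

The CC angiogram is inverted (1 - intensity) and thresholded at mean +
k x SD, with both moments computed over the analysable region (everything
outside the large-vessel and disc masks) using the population (n) SD.
Computing the moments over the analysable region rather than the whole
frame is the more defensible reading — the excluded structures would
otherwise bias the threshold — and a whole-image option is available.
Components are labeled at 8-connectivity by default (4 is available), with
no minimum size by default; both matter for the count and mean-size
metrics, so they are explicit configuration. Per region we report area %
(void pixels over analysable pixels), count (components assigned by
majority pixel membership, exact ties to the macula — deterministic and
free of double counting), and mean size in µm² (total assigned component
area over count, using pitch_x x pitch_y per pixel), so mean size x count
reproduces the total void area exactly.

Two properties anchor this module. First, on an i.i.d. Gaussian-intensity
image the detected area fraction must equal the Gaussian tail 1 - Phi(k):
15.87% at k = 1 and 10.56% at k = 1.25. Second, the k = 1.25 void pixel
set is nested inside the k = 1 set, so void area can only shrink as the
threshold grows — the qualitative behaviour reported for real scans.
Component count is not mathematically monotone under nesting (a component
can split), so the tests assert exact area/pixel-set monotonicity per scene
and the directional effect on the ensemble mean.

## Repeatability statistics

The ICC is ICC(2,1) — two-way random effects, absolute agreement, single
measurement — computed from the two-way ANOVA mean squares, with the
F-based McGraw–Wong 95% confidence interval. Absolute agreement is the
appropriate flavour for same-device inter-visit repeatability because it
penalizes a systematic shift between visits; ICC(3,1) would not. The
interpretation bands are < 0.50 poor, 0.50–0.75 moderate, 0.75–0.90 good,
above 0.90 excellent, with exactly 0.90 falling in "good" under the strict
"> 0.90" reading of the excellent band. Degenerate inputs follow explicit
conventions rather than propagating NaN: identical visits give ICC = 1
with a collapsed CI and a flag; zero-variance differences give a flagged
paired-t with p = 1 (identical visits) or an undefined p (constant
non-zero shift).

Bland–Altman limits are mean(d) +/- 1.96 x sample SD(d) with d = visit1 -
visit2 (orientation configurable). Pearson correlations between each
filtered variant and the unfiltered reference — the guard against a filter
that achieves high ICC by saturating noise — use per-subject two-visit
averages, a Fisher-z confidence interval and a t-distributed p-value with
n - 2 degrees of freedom. No multiple-testing adjustment is applied,
matching the unadjusted per-row reporting convention of the source
analysis. The estimator was validated against a from-definitions
sums-of-squares oracle (agreement to 1e-10 on 1000 random small datasets)
and by simulation at true ICC 0.9 (b = 3, w = 1, n = 14): the mean
estimate lands within 0.05 and the 95% CI covers the truth at its nominal
rate within 3 points.

## The synthetic-scene generator

The generator exists to give the pipeline inputs with *known answers*; it
aims at testability, not biological fidelity.

* **Retinal slabs**: a branching random-walk vessel tree from 4 arcade
  roots (root calibre 40–110 µm, tapering, stochastic branching at 70%
  width) over a capillary texture made by thresholding spatially
  correlated noise at the quantile that realizes the requested coverage
  exactly; defaults put the large-vessel tree at about 3% of the frame and
  the capillary bed at 35%, in the range of healthy widefield scans. The
  DCP variant drops the vessel tree and adds 5 points of capillary
  density.
* **Choriocapillaris**: correlated granular texture (40 µm correlation
  length) darkened by small elliptical voids (mean area 700 µm², i.e. a
  few pixels, matching the small-and-numerous character of healthy flow
  voids) stamped from a deterministic candidate stream until the target
  coverage (default 15%) is met. Because the stream is consumed as a
  prefix, scenes with different targets from one seed have nested void
  sets.
* **Degradations**: radially symmetric multiplicative vignetting (default
  25% at the corners) and speckle modeled as image x (1 + N(0, sigma)) +
  N(0, sigma/2), clipped — a deliberately simple two-parameter model.
* **Cohorts**: the latent metric of subject s at visit v is mu + b_s +
  w_sv with b and w the between-/within-subject SDs, so the design's true
  ICC is b²/(b² + w²). Defaults (n = 14 subjects, 2 visits, b = 0.8, w =
  0.4 percentage points) mirror a two-visit repeatability study in healthy
  eyes, with a between-subject SD taken from the order of magnitude of
  published subject-average SDs and a within-subject SD consistent with
  limits of agreement near +/- 1 point. Subjects keep one anatomy across
  visits (fixed anatomy RNG substream); the latent shift acts on capillary
  density or void fraction, and each visit receives fresh speckle. Every
  generator is a pure function of (spec, params, seed): named RNG
  substreams (anatomy / noise / visit) are derived from the seed, and the
  caller's RNG state is never touched.

What the generator does **not** emulate: true OCTA speckle statistics and
flow decorrelation, projection artefacts from the superficial plexus,
segmentation errors of the depth slabs, motion artefacts, and realistic
capillary morphology (the texture has the right coverage and scale but not
the connective geometry of a plexus). A pipeline that passes on these
scenes is therefore validated for its *measurement logic* — geometry,
thresholds, statistics, determinism — not certified against device data.

## Numerical choices and degenerate inputs

* FFT convolution throughout (via EBImage), with reflect padding applied
  before and cropped after, so no wrap-around reaches valid pixels.
* Strict ">" threshold comparisons carry epsilon guards (1e-8 for the
  local-mean binarizer on [0,1] intensities, 1e-12 for the flow-void
  threshold) so constant inputs land exactly on the documented
  tie-to-background behaviour.
* Discrete Gaussian-derivative kernels are mean-corrected so they
  annihilate constant images exactly; min-max rescaling treats a response
  range below 1e-10 as flat and returns zeros instead of amplifying
  roundoff.
* Population SD (divisor n) for the flow-void threshold: at image scale
  the difference from n - 1 is negligible, but fixing it makes runs
  bit-reproducible and documentable.
* An empty effective region (PD denominator) or an empty analysable CC
  region is an explicit error, never NaN.

## Problem sizes used by the tests and the acceptance script

Single-image checks (Gaussian-tail calibration, PD recovery, large-vessel
Dice, partition geometry) run at the native 800 x 534 grid. Ensemble checks
trade grid for replication: the threshold-monotonicity ensemble uses 50
scenes on a 200 x 134 crop at native pitch, and the 14-subject two-visit
cohort for the end-to-end determinism check renders the full 15 x 9 mm
field at 400 x 267 (pitch doubled), which exercises every stage — all
physical parameters are specified in millimetres or micrometres and convert
through the pitch — while keeping a full double run inside a few minutes.
Statistical calibration (ICC oracle agreement, parameter recovery, CI
coverage) works on latent metrics directly and needs no images.

## Known limitations

* The three published filters are under-specified at the source (no
  Frangi constants, a unitless Gabor wavelength, a Bayesian filter defined
  by citation); our defaults are documented interpretations, exposed as
  configuration, and measurements taken under different settings are not
  interchangeable — which is, in fact, the central message of the
  repeatability analysis this package operationalizes.
* Flow-void count and mean size are sensitive to connectivity and minimum
  component size; comparisons are only meaningful at fixed settings.
* ICC confidence intervals are F-approximations; at n = 14 their coverage
  is near-nominal in our simulations but they are not exact.
* The synthetic generator's latent-shift mechanism changes the capillary
  quantile threshold between visits of one subject, so visit-to-visit
  anatomical variation is global rather than local.
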