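---
title: "Retrospective quantification of nuclear translocation: methods and design"
author: "retrotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective quantification of nuclear translocation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotrack)
```

## The retrospective idea

Live-cell reporters of nucleo-cytoplasmic shuttling proteins (STAT
transcription factors being the canonical example) are typically imaged in a
single fluorescence channel: a nuclear counterstain cannot be added without
perturbing the cells. That makes prospective per-frame segmentation hard —
before stimulation the nucleus is often the *dim* region of the cell.

`retrotrack` implements the retrospective alternative: image the field live,
then fix and stain the same field at the end point. The fixed nuclear stain
gives a high-contrast segmentation; the masks are propagated *backwards*
through the live series after registration. Cell identity is fixed by the
end-point masks — there is no tracking step, which is precisely what makes
the approach robust for mostly stationary cells and is also its main
assumption: a cell that moved during the course invalidates its own mask.
Detecting such cells automatically is the job of the mask classifier.

## Registration

Frames are aligned by integer-pixel translation maximizing the normalized
cross-correlation (NCC) over the mutually *valid* overlap of the two images.
Border bands exposed by a shift are tracked in a validity mask, not filled
with zeros, so they never bias later statistics and never contribute to
subsequent correlations. All candidate shifts within `maxShift` (default 20
px; a generous bound for stage drift between 10-minute frames) are scored at
once using FFT cross-correlations of the images, their squares and their
masks, which makes the exhaustive search exact and fast.

The last frame is registered to the fixed target-protein image; each earlier
frame is registered to the already-registered next frame, because adjacent
frames are most alike. Since every reference in that chain already sits in
the fixed coordinate system, the shift found for frame *i* is directly its
cumulative shift.

Numerical choices: candidate shifts whose overlap covers less than 25% of
the image are excluded; correlation ties (within 1e-9) are broken by the
smallest |dr|+|dc|, then row-major order, so results are deterministic; a
constant image has no defined correlation and is an error. Only translation
is modelled — NCC template matching recovers translations, and rotation of
whole fields is not a failure mode of motorized stages; rotation *of
individual cells* is handled by the mask classifier instead.

## Segmentation

Nuclei come from the fixed nuclear stain in five steps: Laplacian-of-Gaussian
(LoG) filtering at scale `logSigma` (default 3 px, matched to nuclear radii
of roughly 8–15 px; exposed in the configuration), whose negative response
band traces a closed contour just inside each nuclear edge; a 1-px closing
and flood fill of those contours; intersection with the Otsu foreground of
the stain (the combination operator — mask intersection — suppresses
noise-driven fills); distance-transform watershed splitting of touching
candidates; and a size filter removing components below `minAreaFraction`
(default 0.5) of the mean candidate area. The mean is computed per field,
after watershed splitting, so the filter adapts to magnification. An
absolute 30-px floor and a foreground-contrast guard (candidates must exceed
the remaining image by two standard deviations) keep noise specks from ever
entering the relative filter, so a field without nuclear signal returns an
empty map with a warning rather than artifacts.

The Otsu threshold is computed on the histogram of valid pixels only
(registration borders excluded), exhaustively maximizing the between-class
variance; integer images are binned at integer levels, continuous ones into
256 bins.

Cytoplasm is assigned from the *first registered* target-protein frame —
the frame with the strongest cytoplasmic signal, and registered because the
masks live in the fixed frame of reference. Its Otsu foreground is
partitioned among cells by seeded watershed (nuclei as seeds), and each
cell's cytoplasm is the intersection of its watershed territory, the
foreground, and the Euclidean dilation of its nucleus by `d` px (allowed
6–20), minus every nucleus. Nuclear masks are eroded by a Euclidean disk of
radius `e` px (allowed 2–6) before any intensity is measured, to cut
cross-contamination across the nuclear boundary. Both structuring elements
are Euclidean disks. `d` and `e` are deliberately *not* auto-selected: the
difference-variation descriptor (below) is the tool for comparing settings.

Cells touching the image border, or a pixel that is invalid in any
registered frame, were not observed completely and are excluded from
quantification.

## The s.d.-vs-mean mask classifier

A mask that has slipped off its nucleus straddles compartments and image
structure of different brightness, which inflates the standard deviation of
the pixels it covers far more than their mean. Over a stationary control
population (cells imaged once live, then fixed), per-nucleus s.d. is close
to linear in the mean, so a robust line is fitted by iteratively reweighted
least squares — bisquare weights, tuning constant 4.685, scale 1.4826 × MAD,
iterated to a relative coefficient change below 1e-8 (at most 50
iterations). The stored scale is the weighted RMSE of the robust residuals.

Classification uses a pointwise *prediction* band for a new observation,

$$\mathrm{up}(x) = \hat\beta_1 x + \hat\beta_0 + t_{1-\alpha/2,\,n-2}\; s
\sqrt{1 + \tfrac1n + \tfrac{(x-\bar x)^2}{S_{xx}}},$$

not a mean-response confidence band: individual nuclei are admitted into the
band, and a confidence band on the line would be far too narrow to contain
them. With the default `alpha = 0.005` (a 99.5% band) roughly the advertised
fraction of genuinely stationary nuclei falls inside. Only the *upper*
boundary gates the decision — mismatch inflates the s.d., so points below
the line are matched; negative band values at small means are not clamped.
Each cell is classified from its **first-frame** statistics (masks derive
from the end point, so mismatch accumulates toward the first frame) and
later frames inherit the label.

Known blind spot: a mask lying entirely on *flat background* (for example a
cell that moved completely away) has a *low* s.d. and passes the upper-band
gate. The control-population design makes such masks rare, and their traces
are extreme enough that median/percentile population summaries are
unaffected, but per-cell consumers should also consult `shapeQC()` and the
responder logic rather than the class label alone.

The artificial-mismatch generator (`makeMismatch`) rigidly rotates and
translates a mask and intersects it with the original, emulating moved and
undersized masks; it is the validation tool for the classifier and for the
CV-versus-shift behaviour checked in the test suite.

## Descriptors

With per-cell nuclear mean $I_i$ (over the eroded mask) and cytoplasmic mean
$C_i$ at frame $i$ (frame $i$ at $i \times 10$ min by convention; kinetic
times are reported as minutes elapsed since the first frame):

* **N:C ratio** $(I_i/C_i) / (I_1/C_1)$ — normalized to 1 at time 0.
* **Nuclear accumulation (NA)** $I_i / I_1$ — normalizes away expression
  differences; insensitive to the cytoplasmic mask.
* **Nuclear increment (NI)** $\Delta I_i = (I_i - I_{i-1}) / I_1$ — a speed
  proxy; the telescoping identity $\sum_{i\le k}\Delta I_i = \mathrm{NA}_k -
  1$ holds exactly and is asserted in the tests.
* **Difference variation** $|V_1 - V_2| / (V_1 + V_2)$ — normalized
  disagreement between two measurements of the same quantity (e.g. two
  $(d, e)$ settings); the more reliable descriptor yields the smaller value.

All three kinetic descriptors are invariant under a global multiplicative
gain. Responders are called against the 95th percentile (linear
interpolation between order statistics) of the **un-normalized** pre-treatment
N:C ratios — using normalized ratios would double-normalize and make the
threshold meaningless. The time of maximal import speed re-computes NI on a
20-minute grid (two-frame differences at the default 10-minute interval),
because single-interval NI is noise-sensitive; ties — including the case of
an inflection sitting exactly on a grid boundary — go to the earliest grid
time, with increments within a relative 1e-6 treated as tied so floating-
point noise cannot flip the rule.

## The synthetic-field generator

`simulateField()` renders the full experimental design with known ground
truth: cells as concentric nuclear/cytoplasmic ellipses (nuclear radius
10 ± 1 px, cytoplasmic 18 ± 1.5 px on a 512 × 672 12-bit frame), per-cell
log-normal expression (meanlog log 900, sdlog 0.35), a cytoplasm-dominant
baseline (nuclear:cytoplasmic intensity ratio 0.9), and 13 frames at
10-minute intervals. Responders (default 80%) follow a delayed logistic

$$\mathrm{NA}(t) = 1 + (F-1) \,/\, (1 + e^{-k (t - \mathrm{lag} -
t_{1/2})}),$$

the minimal curve reproducing a lag (~20 min), an acceleration and a
plateau; defaults lag 20 ± 5 min, $t_{1/2}$ 40 ± 10 min, $k$ 0.12 ± 0.02
min⁻¹, plateau fold 3 ± 0.5 (truncated per cell so the conserved cytoplasm
cannot be driven negative). Cytoplasm depletes conservatively — each cell's
total fluorescence above background is constant at every frame, exactly, in
noise-free rendering — and the perinuclear pool depletes first
(`gradientShift`), because the spatial redistribution of the cytoplasmic
pool during import is what makes the cytoplasmic mean sensitive to the mask
extent in real data. A default 3.5% of cells move (2 px/frame) and rotate
(3°/frame), matching the few-percent motile fraction typical of adherent
cultures; global stage drift is configurable. The fixed target image is the
final frame under a smooth random multiplicative dimming field (mean 0.7,
spatial unevenness 10%) emulating fixation-induced, spatially uneven
fluorescence loss — a deliberate stress test for registration. The fixed
nuclear stain is a high-contrast rendering of the nuclei. Noise combines an
additive Gaussian floor (8 counts), a Poisson-like signal-dependent term
(gain 1) and a multiplicative 5% texture; the texture term is what gives
the control population its near-linear s.d.-vs-mean relationship.
Photobleaching is off by default: a solvent-control time course shows no
systematic fluorescence loss at these exposures.

What the simulator does **not** emulate: optics (no PSF, no defocus),
mitosis and cell division, non-rigid cell deformation, structured
autofluorescence, and cell crowding (cells are placed without cytoplasmic
overlap). Passing tests therefore demonstrate the correctness of the
*computational* pipeline under the stated imaging model, not performance on
confluent or dividing cultures.

## Problem sizes and reproducibility

The test suite and the acceptance script validate, end to end: exact
recovery of 50 random shifts in [−15, 15]² (noise-free, and with additive
noise at 5% of the dynamic range) on a 256 × 336 frame; count-exact
segmentation of 30 planted nuclei with IoU ≥ 0.7; a ~500-nucleus control fit
(five 100-cell control fields) with held-out stationary retention and
rejection of masks shifted 1.2 nuclear radii; CV-versus-shift monotonicity
over six shift levels in 60 cells; the difference-variation comparison over
~200 cells and two $(d, e)$ settings; and recovery of a configured plateau
fold of 3 and a configured 60-minute inflection (noise-free, unquantized
rendering) in 60 responders. These sizes were chosen as the smallest at
which the corresponding statistics are stable; all randomness is seeded, and
`simulateField()` is bit-reproducible given its seed.

## Limitations

Beyond the simulator's scope above: identity is only as good as the
end-point masks, so fields with substantial motility need the classifier's
labels taken seriously; the classifier is blind to masks over flat
background (see above); only integer-pixel rigid translation is corrected;
and `d`/`e` selection is left to the difference-variation tool rather than
automated, since the right trade-off depends on cell morphology.
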