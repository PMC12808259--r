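---
title: "Counting gunshot residue on fabric and tape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting gunshot residue on fabric and tape: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrquant)
```

## The measurement problem

Close-range firearm discharge deposits a cloud of dark residue particles on
the target surface. On a bright, finely woven fabric the particles are
conspicuous under visible light; on dark denim they only regain contrast in
infrared, where the dye reflects much more than the residue. In both cases
the photograph is a superposition of

* a smooth illumination field (flash falloff, folds) — very low spatial
  frequency,
* the fabric's own texture (weave or twill periodicity, wash patches) —
  concentrated, for woven fabric, in narrow frequency bands,
* the particles themselves — compact dark spots a few pixels across, whose
  spectral energy is spread over the mid band,
* sensor noise.

The quantification model is therefore linear filtering in the 2-D Fourier
domain to remove the first two components, followed by thresholding and
connected-component counting of what remains, and a purely geometric area
conversion `A = l_pixel^2 * n_pixel` where `l_pixel` is the physical edge
length of a pixel. The two headline quantities per image are the particle
count and the total particle area (in pixels and, when calibrated, in mm²).

The pipeline order is fixed: filter, threshold, label, size-filter,
summarize. Filtering must precede thresholding because the threshold's whole
job is to separate particles from an already-flattened background; the size
filter operates on labelled regions, so it necessarily follows labelling.

## Frequency filters and their parameters

Filters are radially symmetric masks over centred frequencies, with cutoffs
in **cycles per image** so a preset transfers across resolutions. Two
profiles exist:

* hard edge (`transition_width = 0`) — an ideal filter, used in oracle tests
  because its effect on single Fourier modes is exactly predictable;
* Gaussian edge (`transition_width > 0`) — the default in analysis, a normal
  CDF ramp that limits spatial ringing around high-contrast particles.

The DC bin is forced to zero in every mask, so filtered output is mean-free
before re-normalization.

Defaults, chosen to suppress the synthetic textures described below and
validated against their ground truth:

| fabric | filter | low_cut | high_cut | transition |
|---|---|---|---|---|
| white cotton | high-pass | 8 | — | 4 |
| denim | band-pass | 6 | 110 | 4 |

`low_cut` sits above the illumination gradient and coarse wash structure
(≤ 4 cycles) for both fabrics. For denim, `high_cut` must separate two
things that live close together at high frequency: the twill periodicity
(at radius ≈ 120 for the default twill of 85 cycles along each axis) and the
high-frequency tail of the smallest particles. Cutting as low as the twill
band permits (e.g. 64) measurably truncates 1-pixel-radius particles —
recall drops by roughly 10% — while 110 keeps them intact and still
attenuates the twill to under 1% of its amplitude through the Gaussian edge.
Real fabrics will differ: the presets are data, not code, and both the
config file and the CLI flags override them per sample.

After filtering, the real part is affinely mapped to [0, 1] (minimum to 0,
maximum to 1) so that manual thresholds mean the same thing for every image;
a constant pre-normalization result maps to all zeros. The cost of this
choice is analysed next.

## Thresholding: Otsu plus a plausibility guard

`threshold = "auto"` selects the threshold by Otsu's between-class-variance
criterion on a 256-level histogram. Otsu presumes a meaningfully bimodal
histogram, and min–max re-normalization creates a subtle failure mode: an
image containing **no** residue at all is stretched so that its noise spans
the full scale, and Otsu will happily split that noise near its median,
flagging about half the frame as "dark". AUTO therefore accepts the split
only if the resulting foreground covers at most `max_dark_fraction`
(default 0.25) of the pixels — residue plausibly covers a small minority of
a forensic photograph — and otherwise returns an empty mask (threshold 0).
A constant image likewise yields an empty mask. Manual thresholds are always
honoured exactly as given; the guard is an AUTO heuristic, not a clamp.

Foreground is defined as intensity **strictly below** the threshold, so the
"white areas" of the segmented image are the dark spots of the photograph.

## Counting and the size floor

Connected components are computed by a two-pass union-find labeller
(compiled, 4- or 8-connectivity; the default is 8, the standard choice for
blob-like regions, with 4 available for sensitivity analysis). Per-particle
pixel count, centroid and half-open bounding box come from the label image;
labels are assigned in raster order and survive size filtering unchanged.

`min_pixels = 2` by default: single dark pixels at these imaging scales are
overwhelmingly sensor noise or stray fibres. The floor is configurable;
raising it trades inclusion of faint residue against false speckles, and the
count is provably non-increasing in it. Particles touching the image border
are kept — close-range patterns commonly run off the frame.

## Tape lifts

Developed tapes carry violet spots on a pale background. The scan is reduced
to the HSV value channel, `V = max(R, G, B)` (hexcone convention), which is
invariant under any global hue rotation — so the exact developed colour is
irrelevant — and then thresholded and counted without frequency filtering,
tape backgrounds being nearly uniform. A greyscale image handed to the tape
pipeline is an error pointing to the fabric pipeline, and vice versa for
colour input.

Greyscale conversion of colour photographs uses fixed Rec. 601 luma weights
(0.299, 0.587, 0.114): camera "monochrome" modes vary and are rarely
documented, so a fixed standard keeps results reproducible.

## Calibration

`l_pixel` (mm per pixel) is supplied by the user — from a scale bar, a known
object, or the capture geometry. No automatic detection is attempted; area
figures are simply omitted when the calibration is absent, and the pixel
totals are always reported alongside so uncalibrated images remain
comparable to each other.

## Rater statistics

Visibility is scored 0–5 (`none_visible`, `minimal`, `slight`, `moderate`,
`considerable`, `substantial`). Agreement among a fixed panel of raters each
scoring every image once is the Shrout–Fleiss ICC(3,1) — two-way mixed
model, single measures, consistency:

ICC(3,1) = (MS_rows − MS_error) / (MS_rows + (k − 1) MS_error)

with mean squares from the subjects × raters ANOVA (interaction as error).
Consistency means a rater who is uniformly stricter by a constant offset
does not lower agreement; the absolute-agreement variant ICC(2,1), which
does penalize offsets, is available via `type = "agreement"`. A constant
matrix has zero total variance and the ICC is reported as undefined rather
than silently returned.

The conventional verbal bands overlap in print (0.4–0.69 "fair" against
0.6–0.74 "good"); a classifier must be single-valued, so the boundary is
placed at 0.60 — the good band's stated lower edge — giving
fair = [0.40, 0.60), good = [0.60, 0.75), excellent = [0.75, 1].

The independent-samples t-test defaults to the pooled-variance (Student)
form, the usual referent of the phrase, with Welch behind a flag; both are
two-sided at α = 0.05. Two identical constant samples are the defined
degenerate case (t = 0, p = 1); constant samples with different means are an
error, not an infinity.

## The synthetic scene generator

There is no public corpus of residue photographs with per-particle ground
truth, so validation runs on a forward model that reproduces the statistical
structure the pipeline assumes:

* **white cotton** — bright base (0.85) + low-frequency illumination cosine
  (amplitude 0.05, 1–2 cycles) + fine separable weave (amplitude 0.02 at 180
  cycles) + Gaussian noise (sd 0.02);
* **denim** — base 0.55 in IR / 0.30 in VL (denim reflects infrared far
  better than visible light), coarse wash patches (three cosines ≤ 4 cycles,
  amplitude 0.06 each), a diagonal twill sinusoid (amplitude 0.15 at 85
  cycles per axis), gradient and noise as above;
* **tape** — pale near-uniform RGB base with violet spots;
* **particles** — discs with radius uniform in [1, 3] px darkened to
  0.05–0.15, centres drawn from an isotropic bivariate normal (scale:
  `dispersion`, default a quarter of the frame) around the central defect,
  rejection-sampled to the frame and, by default, to pairwise non-overlap
  with a 2 px guard band so the ground-truth count is exact;
* **blood** — an accreted random-walk blob plus satellite droplets; VL
  renders it near-black (wet blood additionally with sparse specular flash
  highlights at 0.95), IR renders it mid-grey with dry (0.55) strictly
  lighter than wet (0.35). Particles are painted on top so residue stays
  visible over blood, as it does through a 700 nm IR filter.

All intensities and frequencies sit in one constants block
(`scene_defaults()`); they encode ordinal facts about the materials — denim
brighter in IR, dry blood lighter than wet in IR, particles dark in both
modalities — not measured reflectances. Every stage derives an independent
RNG substream from the scene seed and restores the caller's RNG state, so
scenes are byte-reproducible whether stages run standalone or together.

What the generator deliberately does **not** model: physically based
reflectance, JPEG/demosaicing artefacts, depth-of-field and motion blur,
fabric folds and 3-D drape, irregular particle shapes, overlapping particle
clusters (available behind `allow_overlap` for under-counting studies), and
any dependence of the pattern on muzzle distance or ammunition. Passing the
synthetic suite therefore demonstrates the pipeline's correctness on images
that satisfy its assumptions, not field performance on arbitrary
photographs — on real material, the per-fabric parameters are expected to
need the same individual adjustment the config file exists for.

## Numerical choices and degenerate inputs

* FFT filtering uses the unshifted DFT grid with the mask built directly in
  that layout; the inverse transform's imaginary residue (≈ 1e-16) is
  discarded. An O(N⁴) direct-sum DFT serves as the test oracle at 8×8.
* Hard-edge masks use strict inequalities (`r > low_cut`, `r < high_cut`);
  a bin exactly on a cutoff is attenuated. With the Gaussian edge the
  question does not arise.
* Min–max re-normalization maps a constant filtered image to all zeros
  rather than dividing by zero.
* 1×N images cannot be meaningfully filtered and are rejected.
* Greedy one-to-one matching scores detections against truth: a detection
  matches a particle if its centroid lies within the particle radius + 1 px;
  pairs are taken in order of increasing distance. F1 from the resulting
  TP/FP/FN. This matching exists only for validation; nothing in the
  measurement pipeline depends on it.
* Particle placement retries up to 600 proposals per requested particle and
  fails loudly (suggesting fewer particles or a larger frame) rather than
  silently under-filling.

## Problem sizes in the test suite

Unit tests run on 8–256 px frames where exactness is the point (DFT oracle
at 8×8, labelling oracle at 32×32 over hundreds of random masks, ICC oracle
on 10×3 matrices). End-to-end recovery runs at the package's reference scale
of 512×512 with 100–2500 planted particles on white cotton (count within
±5% on every scene) and 200 particles on denim across ten seeds (F1 ≥ 0.9,
and strictly above the unfiltered baseline on at least nine). These sizes
were chosen as the smallest at which texture, particle scale and packing
density are cleanly separated in frequency space; everything is generated at
run time from seeds.

## Known limitations

* Touching real particles merge into one component: no watershed splitting.
* Otsu with the plausibility guard can return an empty mask on images whose
  genuine residue coverage exceeds `max_dark_fraction`; extremely dense
  patterns need a manual threshold.
* The consistency ICC deliberately ignores systematic rater offsets; use the
  agreement variant when calibrated absolute scores matter.
* Area in mm² inherits all error in the user-supplied `l_pixel`
  quadratically.
* No inference about ammunition type or muzzle distance is attempted — the
  tool measures patterns, it does not interpret them.
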