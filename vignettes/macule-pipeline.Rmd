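---
title: "Segmenting and characterizing skin macules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and characterizing skin macules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macuseg)
```

## The problem

Flat discolored skin lesions — macules — on the lower limbs of patients
with diabetes are an early, under-recorded sign of vascular damage.
Four phenotypes matter here: *vascular* macules (rounded, reddish to
brown), *petechiae* (pinhead-sized red spots), *trophic-change* macules
(large dark patches from chronic venous insufficiency), and *trauma*
macules (brownish, irregular). `macuseg` locates candidate macules in a
color photograph of a leg, quantifies each one with eleven features,
compares feature distributions between phenotypes, and classifies
macules with a small neural network.

Two properties drive the design. First, skin tone and illumination vary
widely between patients and photographs, so no fixed color threshold
works; every stage therefore derives its thresholds from the image at
hand. Second, macule color only means something *relative to the
surrounding skin*, which motivates the Shade Indices.

## Stage 1 — skin region

Two masks are computed per photograph and combined with a logical AND:

* **Hue band.** The image is converted to hexcone HSV (channels first
  normalized to `[0, 1]`); pixels with hue in the closed band
  `[hue_lo, hue_hi] = [0.01, 0.1]` — red-orange, where human skin of
  any tone lives — pass. The band endpoints are the only fixed color
  constants in the pipeline.
* **Dynamic chroma range.** The image is converted to YCbCr
  (`[Y; Cb; Cr] = [0; 128; 128] + M rgb` on raw 8-bit values) and the
  per-image statistics define the accepted box:
  `min(Cb) <= Cb <= mean(Cb)` and `mean(Cr) <= Cr <= max(Cr)`. Skin is
  redder (high Cr) and less blue (low Cb) than typical non-skin
  backgrounds, so the image's own chroma histogram separates the two
  without committing to any absolute skin color. This is the
  self-tuning that keeps recall stable across light-to-dark tones
  (exercised over a six-tone palette in the test-suite).

The raw conjunction is cleaned by morphological closing (disc radius
`close_radius = 5` px), removal of components smaller than
`min_object_frac = 0.1%` of the image, and hole filling. Cleanup is
deliberately conservative plumbing: it removes speckle, it does not
change which tones count as skin. Interval endpoints are inclusive
throughout, matching the non-strict inequalities of the masks'
definitions.

## Stage 2 — lesion region

Within the skin mask only (background pixels would corrupt every
histogram below):

1. **Luminosity saturation.** The CIELAB L plane — computed through a
   linear RGB-to-XYZ matrix with the two-branch lightness rule, the
   white point taken as the matrix's own image of white so that pure
   white maps exactly to `L = 100` — is linearly stretched so the 2nd
   and 98th percentiles of skin-pixel L map to 0 and 100 (clipped
   outside). Damaged skin darkens, healthy skin lightens.
2. **PCA grayscale.** Each pixel's `(L, a, b)` triplet is projected on
   the first principal component of the skin-pixel cloud, computed
   from the 3x3 covariance eigendecomposition. The component's sign is
   fixed by positive correlation with L, so lesions occupy the *low*
   tail; scores are rescaled affinely so skin spans `[0, 1]`. Unlike a
   fixed luma formula, the projection adapts to whatever color axis
   actually carries the lesion contrast in this photograph.
3. **Dark-tail threshold.** Skin pixels at or below the
   `lesion_fraction = 0.10` quantile of the grayscale are flagged. The
   tie rule is inclusive (`value <= quantile`), which can exceed the
   nominal fraction on quantized or constant images; on continuous
   data the flagged share equals the fraction almost exactly.
4. **Damage percentage** is `100 x |lesion| / |skin|`.

Because the threshold is a quantile, a macule-free leg still flags its
darkest 10% of skin — the damage figure is a *relative* ranking of the
skin surface, not an absolute detector. Conversely, when true macules
cover less than the fraction, all of them are recovered plus a margin
of dark noise; the labeling stage's `min_area = 5` px filter discards
most of that margin.

## Stage 3 — characterization

Flagged pixels are split into 8-connected components (components under
`min_area` dropped). Each region is summarized by eleven features, in
fixed order:

| group | features | convention |
|---|---|---|
| morphologic | area, major axis, minor axis, perimeter, solidity (%) | area = pixel count; axes from the ellipse with identical normalized second central moments (unit-square pixel moment `1/12` included); perimeter = exposed pixel-edge length; solidity = `100 x area / corner-hull area` |
| intensity | maximum, minimum | order statistics of the Stage 2 PCA grayscale over the region, hence in `[0, 1]` |
| shade | ShI_R, ShI_G, ShI_B, ShI_BR | channel-mean ratios macule / healthy ring |

The *healthy ring* realizes "healthy skin around the macule": the
dilation of the region by `ring_width = 5` px, minus every lesion
pixel, restricted to the skin mask. Shade Indices are then

$$\mathrm{ShI}_R = \frac{\overline{M_\mathrm{red}}}{\overline{HS_\mathrm{red}}},
\qquad
\mathrm{ShI}_{BR} = \frac{\overline{M_\mathrm{red}} + \overline{M_\mathrm{blue}}}
                         {\overline{HS_\mathrm{red}} + \overline{HS_\mathrm{blue}}},$$

with green and blue analogous to red, means over raw 8-bit channels.
A macule identical to its surroundings scores exactly 1, and a global
multiplicative illumination change cancels — the property that makes
the indices comparable across skin tones.

Conventions worth noting: the corner-hull solidity uses the polygon
hull of pixel *corners*, so a plus-shaped pentomino gives the exact
hand value `500/7` while a discretized disc approaches 100 from below
at a rate of roughly `1/radius`; the perimeter counts exposed unit
edges, giving 4 for a single pixel and 40 for a 10x10 square. These
are internal conventions — comparing absolute perimeters across
software requires matching estimators.

## Group statistics

`compare_groups()` runs a two-sided pooled-variance Student's t-test
for each of the 11 features over each of the 6 unordered class pairs,
flagging `p < 0.05`, with no multiple-testing correction (matching the
analysis convention this pipeline accompanies). Welch's form is
available via `var_equal = FALSE`. Degenerate inputs are defined
explicitly: equal constant samples give `t = 0, p = 1`; different
constant samples give infinite `t`, `p = 0`.

## The classifier

An 11-input feedforward network with two hidden layers of 4
tanh units and a 4-unit logistic output layer (88 weights and biases)
is trained against one-hot targets by minimizing the sum of squared
errors with Levenberg-Marquardt: the output Jacobian is assembled by
backpropagation and the damped normal equations
`(J'J + lambda I) delta = J'e` solved per step; `lambda` falls by 10x
on an accepted (loss-reducing) step and grows by 10x otherwise, so the
accepted loss sequence is non-increasing, with the Gauss-Newton and
scaled-gradient limits at the two extremes of `lambda`. Weights start
at small uniform values scaled by fan-in. The data are split 60/40
stratified by class; features are z-scored with training-split
statistics only. Held-out accuracy, the confusion matrix, and the
Pearson correlation R between flattened one-hot targets and outputs
are reported, together with the accuracy over all vectors (both
conventions for "accuracy" are reported because either reading is
defensible for small reference experiments).

By default the network trains to convergence on the full training
split. Validation-based early stopping (`val_frac`, `patience`) is
available but off: with 24 training vectors, carving out a validation
subset measurably shrinks the training set without improving held-out
accuracy, and the plain protocol matches the 60/40 description the
architecture comes from. A BFGS optimizer behind the same interface
(`method = "bfgs"`) serves as a robustness fallback.

**What accuracy to expect on synthetic data.** The reference
experiment draws each feature *independently* per class from the
per-class means and SDs of `macule_feature_params()`. Independence is
forced — the reference table carries no covariances — but it is also a
real limitation: in real photographs area, axes and perimeter are
strongly dependent, and classes occupy much tighter regions of feature
space than independent marginals imply. On the synthetic task the
class-conditional distributions overlap substantially for three of the
four classes, so held-out accuracy sits far below the high-90s
reported for real clinical feature vectors, and no classifier could
close that gap on this generator. The acceptance script
(`scripts/acceptance.R`) computes the actual numbers; the petechiae
class, separated from the others by orders of magnitude in area,
remains essentially perfectly recognized.

## The synthetic scene generator

`make_scene()` emulates what the pipeline consumes: a vertical-ellipse
"leg" of one base skin tone (six-tone light-to-dark palette, every
tone inside the Stage 1 hue band) over a fabric-blue background, an
optional multiplicative illumination gradient (default peak-to-peak
amplitude 0.10), additive Gaussian channel noise (default SD 3 of
255 — consumer-camera magnitude), and macules painted as
boundary-roughened ellipses whose colors are the *local* skin color
times per-channel shade factors taken from the per-class reference
values. The renderer selects exactly the requested number of pixels
per macule (sorted jittered elliptical radii), so ground-truth areas
are exact; painting multiplies the illuminated color, so pre-noise
macule/ring ratios equal the painted factors exactly. Everything is
deterministic given the spec's seed.

What the generator does *not* emulate: specular highlights, hair,
shadows and perspective, camera gamma and white balance, spatially
correlated sensor noise, macule texture, and overlapping lesions
(overlap is an error unless explicitly allowed). Passing tests
therefore demonstrate the pipeline's *mechanics* — self-tuning
thresholds, quantile behavior, ratio-based color normalization,
recovery of painted truth — not clinical performance on photographs.

Default problem sizes, chosen to keep every property measurable while
the whole suite runs in well under a minute: scenes of 200x150 px
(legs of ~12,000 px), 12-13 petechiae per recovery scene across 3-4
scenes (30+ regions for shade recovery, 50+ for area recovery), 20
seeds for the classification experiment, 4,000 draws per class for
checking the sampler's moments.

## Numerical and degenerate-input choices

* Achromatic pixels (`V = X`) take hue 0; black takes saturation 0.
* YCbCr clips to `[0, 255]`; the Lab transform runs on `[0, 1]`
  channels; both conventions documented at the API.
* A constant L plane makes the stretch a warning no-op; fewer than two
  distinct skin colors is an error for the PCA.
* Quantile ties are resolved inclusively (all-or-nothing on a constant
  plane).
* Prediction ties at equal output activations resolve to the lowest
  class index — relevant only for the zero-weight edge case.
* A singular LM normal matrix raises the damping rather than failing;
  damping is capped at `1e10`, after which the fit reports the best
  parameters seen.
* Empty rings (a macule filling its entire skin neighborhood) and
  zero ring means are explicit errors rather than NaN indices.

## Known limitations

* The damage percentage is tied to the threshold fraction; it cannot
  fall below the fraction on lesion-free skin, and is best read as a
  within-patient longitudinal signal.
* Features are sampled independently per class in the reference
  experiment (see above); measured covariance from real data would
  sharpen both the group statistics and the classifier ceiling.
* Solidity and perimeter conventions are internally consistent but not
  interchangeable with other software's estimators at small region
  sizes.
* The dynamic chroma range assumes the background is not skin-colored;
  a frame filled entirely by skin leaves roughly a quarter of pixels
  in the accepted box (both chroma conditions halve it) unless the
  image is noise-free.
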