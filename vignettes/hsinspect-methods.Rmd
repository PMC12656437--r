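---
title: "Methods: hyperspectral foreign-object inspection of pork belly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral foreign-object inspection of pork belly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pork belly pieces travel on a conveyor belt between slaughter and packing,
and occasionally pick up foreign objects — plastic fragments (PA/PP, PU,
PEHD, Teflon, nitrile), metal, wood, paper, cardboard, or shreds of a white
conveyor belt. Several of these are nearly invisible to an RGB camera
against meat or fat. A near-infrared line-scan camera (640-pixel line, 224
bands over 942–1723 nm, ~3.5 nm per band) sees material chemistry instead
of colour: polymers and tissue separate by their NIR reflectance
signatures.

The task is pixel-wise segmentation of each hypercube into 13 material
classes: three *background* classes (meat, fat, conveyor belt) that must
never raise an alarm, and ten *contaminant* classes, any of which is a
positive detection. The operational cost model is asymmetric: every false
positive triggers manual inspection, so the pipeline is built end to end
around specificity — a cost-sensitive loss, and a post-processing stack
that deletes implausible detections.

## Sensor conditioning

Line-scan sensors have per-photosite gain and offset variation that shows
up as temporally coherent vertical stripes. With a dark frame $D$ (shutter
closed) and a flat frame $F$ (homogeneous Teflon tile), each acquired image
$I$ is corrected per column $c$ and band $b$:

$$C = (I - D)\,\frac{m}{F - D}, \qquad m = \operatorname{mean}(F - D).$$

`compute_gain()` stores the divisor field $G = (F-D)/m$, so correction is
$C = (I-D)/G$; negative values (read noise around dark level) clamp to 0.
Both frames are per-(column, band) and broadcast over scan lines, which is
exactly the geometry of fixed-pattern noise on a line-scan camera. Because
gain and dark level drift with sensor temperature, pairs are kept in a
`calibration_library()` keyed by temperature and the nearest pair is
selected (ties to the lower temperature).

The first and last 20 bands carry weak signal and are dropped
(`trim_bands()`), leaving 184 bands from roughly 1012 nm to 1653 nm.

Each pixel's spectrum $s$ is then normalized independently.  Two modes are
shipped:

* **minmax** (default): $(s - \min s)/(\max s - \min s)$.  Invariant under
  per-pixel gain *and* offset, which is what actually cancels exposure
  changes, temperature gain drift and multiplicative shadows.  Every
  output spectrum attains 0 and 1.
* **maxdiv**: $(s - \min s)/\max s$ — the division uses the maximum
  alone.  Gain-invariant but not offset-invariant.

"Subtract the minimum, divide by the maximum" admits both readings, so
both are shipped; minmax is the default because shadow attenuation
requires the offset to cancel. Constant (dead-pixel) spectra would divide by ~0; anything with
a denominator below $10^{-8}$ normalizes to the zero vector and is counted
in a warning rather than raising — dead photosites are a fact of life on
real sensors.

## Tiling

Cubes are cut into 20 × 16 tiles (`extract_tiles()`). Training uses 50%
overlap (stride 10 × 8); inference defaults to disjoint tiles for speed.
The final tile along each axis is shifted so it ends exactly at the image
border: no padding, because padded pixels would fabricate spectra and
distort attention statistics. Per-tile predictions are stitched back
(`stitch_predictions()`) by averaging logits over overlaps (majority vote
available), with an error if any pixel is left uncovered.

## The segmentation model

`vitseg_config()` describes a deliberately small Vision Transformer:

* every pixel of the tile is a token; its embedding is the raw 184-band
  spectrum. There is no patch embedding and the width stays 184
  throughout;
* 4 pre-norm transformer blocks, each: LayerNorm → 8-head self-attention
  over the 320 tokens (head dimension 184/8 = 23) → residual, then
  LayerNorm → 2-layer GELU MLP (hidden 736 = 4 × 184, the usual ViT
  ratio — the width was an open choice) → residual;
* a final linear map 184 → 13 per token. No final LayerNorm, matching the
  parameter tally the tests assert (1,637,061 parameters).

No positional embedding is used by default: the signal is almost entirely
spectral, and leaving positions out makes the network exactly
permutation-equivariant in its 320 pixels — a strong structural property
the test suite checks bit-tight in double precision. A learned 320-entry
positional table is available as a config option for experiments.

Ties at the final argmax resolve to the lowest class index. Because
background classes come first in the canonical order, a perfect tie falls
to "meat" — deterministic and aligned with the pipeline's false-positive
aversion. Dropout is fixed at 0 (the training recipe does not use it);
the config field exists but only 0 is accepted.

The forward and backward passes are implemented in single-precision
RcppArmadillo (a double-precision instantiation backs the finite-difference
gradient checks). Training is exactly reproducible for a given seed:
single-threaded, fixed shuffling, no atomics.

## Training

`train_config()` defaults to the production recipe: AdamW
(weight decay 2e-4, applied to linear weights only), peak learning rate
1e-3, 24 epochs at batch size 520 tiles, linear warm-up over 3 epochs
followed by polynomial decay to zero. The decay exponent defaults to
1.0 (linear decay, the simplest polynomial) and is configurable.

The loss per labelled pixel is label-smoothed cross-entropy scaled by a
penalty factor:

$$L = W[t, \hat y] \cdot \Big(-\sum_c q_c \log p_c\Big), \qquad
q = (1-\varepsilon)\,\mathbf 1_t + \varepsilon/13, \quad \varepsilon = 0.3,$$

where $\hat y$ is the current argmax. $W$ penalizes the operationally
expensive mistakes: true meat/fat predicted as any contaminant costs
`w_high` (default 2.0), true conveyor belt predicted as a contaminant
costs `w_low` (default 0.5), everything else 1. The penalty *structure*
is part of the method; the numeric weights are package defaults exposed
in the configuration. $W$ is
applied as a constant factor (no gradient flows through the argmax); the
alternative expected-cost formulation is deliberately not implemented so
there is exactly one well-tested loss path. Pixels labelled 255
(unannotated) stay in the input for spatial context but are excluded from
the loss and from accuracy metrics.

## Post-processing

Two false-positive filters run after the model, by default rules first,
then erosion:

**Spectral rules** (`apply_spectral_rules()`), with $I(w)$ the normalized
intensity at the band nearest $w$ nm:

1. predicted PEHD, $I(1225.5)-I(1211.5) > I(1026)-I(1012)$ and
   $I(1411)/I(1407.5) < 1.04$ → relabel fat;
2. predicted PEHD, $I(1117) > I(1099.5)$ → relabel conveyor belt;
3. predicted PA-PP, $I(1225.5)-I(1215) < I(1232.5)-I(1012)$ → relabel
   meat.

Design decisions the rules required:

* rules evaluate on the *normalized* cube — the representation the
  model saw;
* rule 3 genuinely pairs 1232.5 nm with 1012 nm. The asymmetry is part
  of the rule's definition and is kept as-is rather than "fixed";
* rules 1 and 2 can both fire on one pixel; rule 1 wins. All rules read
  the original prediction (no chaining), so a second application is a
  no-op — asserted as an idempotence test;
* a numerically zero denominator at 1407.5 nm makes the ratio clause
  false.

**Morphological erosion** (`erode_and_reclassify()`): per contaminant
class, the binary mask is eroded with the full 3 × 3 structuring element,
pixels outside the image counting as background. Whole blobs without a
3 × 3 core (2 × 2 specks, 1–2 px ribbons) disappear; rim pixels of
surviving blobs are also stripped. All removed pixels are relabelled to
the fallback class (fat) — the removed rim has to receive *some* label,
and detections are meant to shrink to their most confident interiors.
Erosion is per class, not on the union mask, so two adjacent thin blobs
of different classes cannot keep each other alive. Blob analysis
throughout the package uses 8-connectivity, since thin diagonal ribbons
would shatter under 4-connectivity. Both primitives are implemented in
C++ in this package: the border convention (outside = background) and
8-connected labelling are load-bearing semantics that available image
libraries did not match.

Both filters only ever remove contaminant pixels, so the contaminant
count is monotone non-increasing through every arm — an invariant the
tests assert end to end.

## The synthetic scene generator

Real acquisitions are optional; every test runs on synthetic scenes
(`make_spectrum_library()`, `render_scene()`). The generator emulates the
statistical structure the pipeline assumes:

* **Spectra**: 13 mean reflectance curves, each a smooth baseline plus
  2–4 Gaussian bumps/dips; the parameters are design constants, not
  digitized measurements of real materials. Separability is an asserted
  invariant: after minmax normalization the closest canonical pair is
  ~14° of spectral angle, more than 3× the mean intra-class spread under
  per-pixel jitter. Per-pixel variability rescales each bump
  independently — a shape change that survives normalization — plus a
  lognormal albedo factor and additive read noise that do not.
* **PEHD and its confuser**: the PEHD curve carries the features the
  rules probe — the 1205/1230 nm inflection, a 1012→1026 nm rising
  flank, a dip at 1117 nm, and a reflectance step above ~1408 nm that
  puts its normalized 1411/1407.5 ratio near 1.23, far above the 1.04
  threshold, so true PEHD never fires rule 1 or 2. A 14th curve,
  `pehd_hard`, is fat plus a weak copy of the inflection; per pixel it
  drifts a uniform amount $u$ towards PEHD *everywhere except the three
  rule windows*, which remain fat-like at every $u$. High-$u$ pixels fool
  whole-spectrum classifiers (a nearest-centroid classifier mislabels
  them as PEHD at a rate tunable through `hard_u_max`) while rule 1
  reclaims them as fat — with rule 2 as backup where noise pushes the
  ratio over 1.04, which also gives the ratio its intended straddling
  behaviour around the threshold.
* **Sensor model**: raw = dark(T) + gain(T) · stripe(column) ·
  envelope(band) · reflectance · shadow + read noise, with lognormal
  per-column stripes (σ = 0.05), an affine temperature response over
  10–55 °C, a smooth multiplicative shadow field, and noise-free
  calibration frames generated from the same dark/stripe/envelope — so
  flat-field correction inverts the forward model exactly up to read
  noise, and normalization cancels temperature, exposure and shadows.
  This consistency is asserted at 1e-6 relative error in the noise-free
  configuration.
* **Scenes**: an elliptical belly split into fat and meat zones (either
  side up), contaminants as rectangles, ellipses or thin wavy ribbons
  stamped two pixels wide along the scan line (the physical floor: a
  1 mm² object spans at least two pixels), and clean scenes that carry
  hard fat-like PEHD patches — the empirically dominant false-positive
  mode — instead of real contaminants.

What the generator does *not* model: the halogen illuminant's absolute
radiometry, optical point-spread/diffraction mixing at blob borders, and
annotation noise. Passing tests therefore demonstrate that the pipeline's
logic is correct under its own assumptions — clean per-pixel spectra with
well-separated classes — not that the trained weights would transfer to
real acquisitions, where boundary mixing and annotation imprecision raise
the difficulty considerably.

## Desk-scale experiment sizes

The headline experiment (`run_synthetic_benchmark()`, also what
`scripts/acceptance.R` reruns) uses sizes chosen so the full loop —
render, calibrate, train, predict, post-process, evaluate — runs on a
single CPU core in minutes while keeping every moving part of the method
exercised:

* scenes are 128 × 160 pixels (the geometry generalizes; 640 × 1000 is
  configurable);
* 200 contaminated training scenes; from each, the 5 most
  contaminant-rich disjoint tiles plus 1 background tile (≈1200 tiles);
* 3 epochs at batch 24, peak learning rate 2e-3 with 1 warm-up epoch —
  a compressed version of the 24-epoch/batch-520 production recipe,
  adequate because the synthetic classes are close to linearly separable
  in the normalized spectra;
* 6 held-out contaminated scenes for mIoU, 50 clean scenes (10% of fat
  area as hard confuser patches) for the false-positive arms, 12
  contaminated scenes for blob retention.

mIoU is averaged over the classes present in each reference mask, and
true-positive accounting is at blob level: a ground-truth blob counts as
detected if any predicted contaminant pixel (of any class) overlaps it —
the operational goal is flagging, not per-class identification. Retention
is measured over blobs that own a 3 × 3 core, because coreless blobs are
removed by the erosion stage *by design*.

## Numerical choices, in one place

* argmax ties → lowest index (background-favouring); nearest-band ties →
  lower band; calibration temperature ties → lower temperature.
* normalization degeneracy guard: denominator < 1e-8 → zero spectrum +
  warning; rule-1 ratio guard: denominator < 1e-8 → clause false.
* LayerNorm epsilon 1e-5; weight init truncated normal (±2 sd) with
  sd 0.02, zero biases, unit norm scales; AdamW β = (0.9, 0.999),
  eps 1e-8, decoupled decay on weight matrices only.
* flat-field clamp at 0; normalized values clipped to [0, 1] against
  rounding.
* training, rendering and dataset generation are fully seeded; identical
  seeds give bit-identical histories and manifests.

## Known limitations

* Only dropout 0 is supported; the field is config surface, not a knob.
* The penalty values (2.0 / 0.5) and the polynomial power (1.0) are
  configurable package defaults, not fitted or validated quantities.
* The ENVI reader supports data types 4 and 12 and uncompressed files
  only — the formats line-scan NIR cameras actually emit.
* The synthetic generator's intra-class variability and the fat/PEHD
  overlap geometry are stylized; the hard-mode rate is a free parameter,
  not an estimate of any real contamination statistic.
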