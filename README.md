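# hsinspect

Near-infrared hyperspectral inspection of pork belly for foreign objects,
as an R package. Pork belly pieces move along a conveyor belt under a
line-scan NIR camera (640-pixel line, 224 bands over 942–1723 nm); the
package segments every pixel of the resulting hypercube into 13 material
classes — three background classes (meat, fat, conveyor belt) and ten
contaminant classes (PA/PP, PU, metal, PEHD, Teflon, nitrile, wood, paper,
cardboard, white belt fragments) — and then aggressively suppresses false
alarms, because every false positive on a production line triggers manual
inspection.

The pipeline, end to end:

1. **Calibration** — flat-field correction with a dark frame `D` and flat
   frame `F`: `C = (I − D)·m/(F − D)` with `m = mean(F − D)`, removing
   fixed-pattern vertical stripes; band trimming to the 184 informative
   bands; per-pixel spectral normalization `(s − min s)/(max s − min s)`,
   which cancels exposure, temperature gain drift and shadows.
2. **Segmentation** — a lightweight Vision Transformer over 20 × 16
   tiles: each pixel is a token whose embedding is its raw 184-band
   spectrum; 4 pre-norm blocks with 8-head self-attention over the 320
   tokens and a 2-layer GELU MLP; a final linear head to 13 classes
   (1,637,061 parameters). Trained with AdamW (lr 1e-3, weight decay
   2e-4, warm-up + polynomial decay, label smoothing ε = 0.3) under a
   cost-sensitive loss `L = W[t, ŷ]·(−Σ_c q_c log p_c)` that charges
   extra for meat/fat → contaminant mistakes.
3. **Post-processing** — three wavelength-inequality rules that reclaim
   spectrally implausible PEHD/PA-PP detections (e.g. predicted PEHD with
   `I(1225.5) − I(1211.5) > I(1026) − I(1012)` and
   `I(1411)/I(1407.5) < 1.04` is relabelled fat), followed by 3 × 3
   morphological erosion that deletes every blob without a 3 × 3 core.
4. **Evaluation** — TP/FP accounting at image, blob and pixel level per
   post-processing arm, plus mIoU.

Everything runs on synthetic hypercubes from the built-in scene generator
(13-class spectra, stripe noise, temperature/exposure drift, shadows, thin
ribbon contaminants, and a fat-like PEHD confuser mode), so no external
data is needed. ENVI cube I/O (BIL/BIP/BSQ, float32/uint16) and indexed
PNG masks are supported for real acquisitions.

## Worked example

Render a synthetic scene, condition it, and push a prediction through the
post-processing stack:

```r
library(hsinspect)

tax <- hsi_taxonomy()
lib <- make_spectrum_library(seed = 1)
rec <- scene_recipe(height = 64, width = 80, temperature = 40, seed = 5,
                    contaminants = data.frame(class = "pehd", shape = "rectangle",
                                              h = 8, w = 8, row = 30, col = 40))
s <- render_scene(rec, lib)
s$raw
#> <hypercube raw224> 64 lines x 80 samples x 224 bands, 942.0-1723.0 nm, T = 40.0 degC

cube <- condition_sample(s)   # correct -> trim -> normalize
cube
#> <hypercube normalized184> 64 lines x 80 samples x 184 bands, 1012.0-1653.0 nm, T = 40.0 degC
```

The flat-field correction inverts the sensor model: corrected intensities
equal `m ·` reflectance up to read noise, and normalization removes the
temperature gain entirely — the same scene rendered at 10 °C and 55 °C
normalizes to pixel-wise agreement within read noise.

Train the segmenter at desk scale and evaluate the post-processing arms
(this is the package's headline experiment; ~12 min on one CPU core):

```r
b <- run_synthetic_benchmark(seed = 1)
b
#> Synthetic end-to-end benchmark
#>   held-out mIoU:             1.0000
#>   FP images (raw model):     50 / 50 clean scenes
#>   FP images (rules+erosion): 0 / 50 clean scenes
#>   TP blob retention:         29 / 29 cored blobs (100.0%)
```

Read: the raw model false-alarms on every clean scene containing fat
whose spectrum drifts towards PEHD (the hard confuser mode the generator
plants) — 22,302 false-positive pixels over the 50 scenes, all labelled
PEHD; the spectral rules plus erosion silence every one of them, while
every true contaminant blob that owns a 3 × 3 core — the ones erosion is
designed to keep — is still detected. Held-out mIoU is the mean
intersection-over-union over classes present in each scene; the synthetic
classes are fully separable at this training scale, so the model
segments the held-out scenes pixel-perfectly.

A thin CLI over the same functions is installed at
`inst/scripts/hsinspect` (`simulate`, `preprocess`, `train`, `predict`,
`postprocess`, `evaluate`).

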