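---
title: "Methods: NDVI-weighted VIS-NIR fusion and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NDVI-weighted VIS-NIR fusion and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirfuse)
```

## The problem and the model

Fruit-picking vision systems in greenhouses face two coupled problems:
ambient light varies strongly over the day, and the most valuable targets
(ripe blackberries) are nearly black, so in underexposed images they
disappear into the shaded canopy. A registered near-infrared image helps
twice over: photosynthetic tissue reflects NIR strongly (which is also why
the normalized difference vegetation index separates vegetation from
background), and the NIR sensor retains structure where the visible sensor
has crushed blacks.

`fuse_pair()` combines three sources per pixel — the original visible
image `I`, an enhanced version `R'`, and a colour-ratio-preserving NIR
term `FN` — with spatial weights derived from two scene maps:

* the **vegetation index** `VI = (N − R)/(N + R)` and its complement
  `VI' = 1 − clip(VI, 0, 1)`, separating canopy from sky/tarpaulin;
* the **transmission map** `t = clamp((1 − ω) D, t_floor, 1)`, where
  `D = min_c I^c / L^c` is the dark channel of the image normalized by the
  atmospheric light `L`.

`L` is estimated per channel as the maximum visible intensity over the
0.1% of pixels with the lowest vegetation index. In a greenhouse those are
tarpaulin/sky pixels, so `L` measures the scene illumination rather than a
specular leaf highlight. The enhancement operates in the inverted domain:
`R = L + (I' − L)/t` with `I' = 1 − I`, re-inverted as
`R' = 1 − clip(R, 0, 1)`. When the sky region saturates the sensor
(`L ≈ 1`), this reduces algebraically to `R' ≈ I / t` — the classical
divide-by-transmission low-light enhancement — so dark vegetation
(small `D`, hence `t` at its floor) is brightened up to 10×, while sky
(`D ≈ 1`, `t ≈ 1 − ω`) is left to the fusion weights. The final blend
`F = clip(FN + I(1 − w) + R' w, 0, 1)` with `w = t · VI'` keeps the
original image wherever either map vetoes enhancement, and adds
`FN^c = δ N D I^c / ΣI^c`, which multiplies each pixel's RGB vector by a
scalar and therefore cannot change hue or HSI saturation — the mechanism
behind the observed "contrast up, saturation unchanged" behaviour.

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `delta` (δ) | 0.5 | [0, 1] | weight of the NIR term `FN`; near 1 the canopy washes out |
| `omega` (ω) | 0.6 | [0, 1) | enhancement strength through the transmission map |
| `t_floor` | 0.1 | (0, 1] | caps amplification in `1/t` at 10×; prevents division blow-up |
| `light_percentile` | 0.001 | fraction | share of lowest-VI pixels considered for `L` |
| `eps` | 1e-6 | — | guard for all divisions (NDVI denominator, colour ratio, black pixels) |
| exposure threshold | 40 | CIELAB L | mean-lightness split between `low` and `normal` scenes |

The defaults for δ and ω are the operating point for balanced
visualization quality; the exposure threshold of 40 mean-L separates
underexposed from normally exposed scenes.

## Design choices where the design was open

* **Dark-channel domain.** The transmission could be derived from the dark
  channel of the original image or of its complement. The default is the
  **original** image (`dark_source = "original"`): `D = min_c I^c / L^c`
  then lies in `[0, ~1]` (both `I` and `L` live in the same domain), the
  transmission actually varies across the scene, and the saturated-sky
  limit reduces to the classical low-light scheme. Normalizing the
  *complement* by an `L` measured on the original puts `D` far above 1 in
  dark scenes, the clamp pins `t` at 1, and the enhancement stage becomes
  a no-op; that reading is retained behind the flag
  (`dark_source = "complement"`) for comparison.
* **Transmission formula.** `t = (1 − ω) D` is the default; the
  conventional dehazing form `t = 1 − ω D` is available as
  `t_formula = "canonical"`. Both are clamped to `[t_floor, 1]`.
* **Polarity of `R'`.** The enhancement update runs on the inverted image,
  so its output is re-inverted (`R' = 1 − clip(R, 0, 1)`) before entering
  the fusion, giving a normal-polarity enhanced image.
* **Negative NDVI.** `VI' = 1 − clip(VI, 0, 1)` treats negative indices
  (water, snow, clouds) as maximally non-vegetation: such pixels take the
  sky role in the fusion.
* **Ties in the atmospheric-light selection** are broken by row-major scan
  order, and at least one pixel is always selected.
* **Grayscale and colour conventions.** Rec. 601 luminance weights;
  CIELAB through the standard sRGB/D65 transform; HSI saturation
  `S = 1 − 3 min(r,g,b)/(r+g+b+eps)` with black mapped to 0. Metric values
  are convention-dependent in their published uses; all four default
  conventions are stated here and tested against per-pixel references.
* **Contrast scale.** The variance-style contrast definition is reported
  by default as its square root (RMS contrast, the population standard
  deviation of 0–255 intensity): contrast differences of a few units are
  only meaningful on that scale. `mode = "variance"` returns the raw
  variance form.
* **Entropy binning**: 256 uniform bins over [0, 1] with the last bin
  right-closed, so 8-bit levels `g/255` land in bin `g`; per-channel
  entropies are averaged.

## The synthetic scene generator

`generate_scene()` encodes the *ordinal* structure the method exploits,
not photorealism:

* a bright sky/tarpaulin band whose NIR tracks its red channel
  (`VI ≈ 0`);
* foliage with high NIR reflectance (`VI ≈ 0.6–0.8`, comfortably above
  the 0.2 vegetation threshold), plus brown stems;
* berry clusters rendered as overlapping disk "drupelets", disjoint by a
  Poisson-disk placement margin, with ripeness-dependent reflectance:
  ripe near-black, nearly-ripe dark with orange patches, unripe
  green/orange. Orange fruit tissue keeps high NIR reflectance (it is
  living tissue), so its index stays positive and the lowest-VI selection
  still finds the sky.

Two radiometric choices matter:

* **Exposure scales both VIS and NIR.** Ambient light drives both
  sensors; because NDVI is a ratio of co-scaled bands it is then
  exposure-invariant, exactly the property the method relies on to find
  the sky in dark scenes.
* **The tarpaulin carries radiance headroom** (`sky_gain = 3.5` relative
  to the canopy white point, clipped at sensor saturation). The ceiling
  *is* the light source: it saturates at normal exposure and remains the
  brightest region in underexposed shots, as in real greenhouse imagery.
  Without this headroom (uniform scaling of an all-below-white scene) the
  atmospheric light scales down with exposure, no pixel satisfies the
  brightening condition `I > 1 − L`, and no dark-channel method can
  brighten anything — an unrealistic failure mode the generator would
  otherwise bake in.

Gaussian sensor noise (default σ = 0.01) is added to both images after
exposure and saturation, then clipped. Scene geometry depends only on the
seed, so exposure series are pixel-aligned. Fruit geometry is cosmetic;
masks and centre-based boxes `{x, y, w, h, ripeness}` are exact by
construction.

What the generator does **not** emulate: specular highlights, shadows cast
across the canopy, depth-of-field blur, chromatic sensor response,
misregistration between the two sensors, and the IR projector texture of
stereo depth cameras. Tests passing on these scenes show the pipeline is
implemented correctly and behaves as designed under the intended scene
structure; they do not certify performance on real imagery.

## Numerical choices and degenerate inputs

All images are floating point in [0, 1]; 8/16-bit files are normalized by
`2^bits − 1` on read and re-quantized round-half-up on write. Divisions
are `eps`-guarded: zero-reflectance pixels get `VI = 0` (hence sky-like
weight), black pixels get zero NIR term and zero HSI saturation. The
transmission clamp `[t_floor, 1]` bounds the enhancement; the final output
is clipped to [0, 1]. Patch resizing and augmentation share one bilinear
affine resampler with reflected border padding; augmentation composes
reflection → rotation → translation → shear about the patch centre into a
single matrix, so only one resampling pass touches the data. Degenerate
boxes (under 2 px a side after clipping) are skipped with a warning.

## Scope of the evaluation harness

`compare_methods()` contributes data plumbing: it runs each method over a
manifest, collects the four metrics per image, and delegates the all-pairs
mean comparison to `stats::aov` + `stats::TukeyHSD` at α = 0.05. Failing
methods are recorded as missing rows, not fatal errors. Classifier
training (ripeness CNNs, feature-extraction pipelines) is deliberately out
of scope; the patch extraction and augmentation steps produce the inputs
such a classifier would consume.

## Problem sizes used in the shipped checks

The test suite and the acceptance script use sizes chosen for quick,
deterministic desk-scale runs: oracle equivalence of the vectorized
pipeline against a per-pixel scalar reference on 100 random pairs of
8–16 px a side (tolerance 1e-9); metric oracles on 16×16 random images;
the low-light claim surrogate on 20 seeded 128×128 scenes with exposures
0.15–0.30 (fused RMS contrast must strictly exceed the original's on every
scene, with saturation shifts at most 0.05); NDVI-semantics checks at
noise σ = 0.02; and a 5-scene end-to-end CLI run.

## Known limitations

* The method's working range is bounded below: in nearly black scenes
  (exposure ≲ 0.1 here, mean L ≈ 12) even the tarpaulin drops far from
  saturation, the brightening condition `I > 1 − L` fails scene-wide, and
  contrast gains vanish or reverse. This is a property of the algorithm,
  which estimates its light level from the scene itself.
* Absolute metric values depend on grayscale/colour-space conventions;
  comparisons across implementations should re-compute both sides with
  one convention.
* Pairs are assumed registered; no alignment is attempted.
* The enhanced branch `R'` clips to black for pixels darker than `1 − L`,
  which is benign in the fusion (their weight is small) but makes `R'`
  alone unsuitable as a display image in deep shadow.
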