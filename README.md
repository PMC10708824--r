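# nirfuse

NDVI-weighted fusion and low-light enhancement of registered visible
(RGB) and near-infrared image pairs, aimed at fruit and vegetation imagery
taken under difficult greenhouse illumination. Dark fruits such as ripe
blackberries are easily confused with the background in underexposed
images; fusing the NIR band into the visible image while adaptively
brightening the vegetation makes them visible again without over-enhancing
the bright sky/tarpaulin region.

## The method

For a registered pair — a visible image `I` (RGB, values in [0, 1]) and a
near-infrared plane `N` — the pipeline computes:

1. **Vegetation index** (NDVI): `VI = (N − R) / (N + R)` with `R` the red
   channel; `VI > 0.2` marks vegetation, `VI ≈ 0` sky/tarpaulin or soil,
   `VI < 0` water/snow/clouds. Its complement `VI′ = 1 − clip(VI, 0, 1)`
   weights the non-vegetation part of the scene.
2. **Complement image**: `I′ = 1 − I`. Inverting an underexposed image
   produces a haze-like bright image, the domain in which dark-channel
   dehazing doubles as low-light enhancement.
3. **Atmospheric light** `L`: per channel, the maximum of `I` over the
   0.1% of pixels with the *lowest* vegetation index — the brightest
   non-vegetation (sky) pixels, found reliably even when leaves are
   specular.
4. **Dark channel and transmission**: `D = min_c I^c / L^c` and
   `t = (1 − ω) D`, clamped to `[0.1, 1]`. Small `t` means strong
   enhancement.
5. **Enhancement**: `R = L + (I′ − L) / t`, re-inverted to normal polarity
   as `R′ = 1 − clip(R, 0, 1)`. With a saturated sky (`L ≈ 1`) this
   reduces to the classical divide-by-transmission brightening `R′ ≈ I/t`.
6. **NIR term**: `FN^c = δ · N · D · I^c / (I^r + I^g + I^b)`. Being
   proportional to each pixel's own channel value, it brightens without
   changing hue or saturation.
7. **Fusion**: `F = clip(FN + I · (1 − w) + R′ · w, 0, 1)` with weight
   `w = t · VI′`, so enhancement enters where the transmission and the
   non-vegetation weight allow it.

Defaults are `δ = 0.5`, `ω = 0.6`. Quality is quantified with four
standard fusion metrics: RMS contrast (0–255 scale), Shannon entropy
(bits, per channel over 256 bins), CIELAB colorfulness
(`σ_a + σ_b + 0.94 · mean chroma`) and mean HSI saturation.

The package also ships a synthetic greenhouse scene generator (registered
VIS/NIR pairs with ground-truth masks and ripeness-labelled bounding
boxes), exposure labelling by mean CIELAB lightness, 224×224 patch
extraction with geometric augmentation, and batch method comparison with
Tukey multiple-comparison statistics.

## Worked example

```r
library(nirfuse)

# an underexposed synthetic greenhouse scene (or load_pair("vis.png", "nir.png"))
sc <- generate_scene(scene_spec(seed = 42, exposure = 0.2))
exposure_split(sc$pair$vis, image_id = "scene42")
#> # A tibble: 1 × 3
#>   image_id mean_L label
#> 1 scene42    23.6 low

fr <- fuse_pair(sc$pair)
fr
#> <fusion_result> 128x128, delta=0.5, omega=0.6
#>   atmospheric light L = (0.6798, 0.6419, 0.6333)

tidy(fr)
#> # A tibble: 3 × 5
#>   image    contrast entropy colorfulness saturation
#> 1 original     65.7    4.82        15.7     0.444
#> 2 enhanced    116.     1.27         3.64    0.00474
#> 3 fused        93.5    4.89        15.2     0.442
```

The mean CIELAB lightness 23.6 is below the threshold of 40, so the scene
is labelled underexposed. Fusion raises the RMS contrast from 65.7 to 93.5
while the mean HSI saturation stays at 0.44 — the image gets easier to
discriminate without colour distortion. `autoplot(fr)` shows the original,
enhanced and fused images; `write_fusion(fr, "fused.png", debug_maps =
TRUE)` writes the result plus the vegetation-index, transmission and
weight maps.

Batch comparison over a dataset:

```r
manifest <- generate_dataset(10, "scenes", scene_spec(exposure = 0.25), seed = 1)
cmp <- compare_methods(manifest, list(
  original = function(p) p$vis,
  fused    = function(p) fuse_pair(p)$fused
))
tidy(cmp)     # per-metric Tukey mean differences at alpha = 0.05
```

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nirfuse", package = "nirfuse"))')
Rscript "$CLI" synth --n 5 --seed 11 --exposure 0.25 --out scenes
Rscript "$CLI" fuse --vis scenes/scene_001_vis.png --nir scenes/scene_001_nir.png --out fused.png --debug-maps
Rscript "$CLI" metrics fused.png --out metrics.csv
Rscript "$CLI" evaluate --manifest scenes/manifest.csv --out evaluation
```

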