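# NDVI-weighted VIS/NIR fusion with dark-channel-prior low-light
# enhancement.
#
# Pipeline (all in normalized [0,1] space):
#   1. vegetation index VI = (N - R)/(N + R), complement VI' = 1 - clip(VI,0,1)
#   2. complement image I' = 1 - I (invert: dark regions become haze-like)
#   3. atmospheric light L: per-channel max of the VIS image over the
#      fraction of pixels with the lowest VI (least-vegetated, i.e. sky)
#   4. dark channel D = min_c I^c / L^c; transmission t = (1 - omega) D,
#      clamped to [t_floor, 1]
#   5. enhancement R = L + (I' - L)/t, re-inverted: R' = 1 - clip(R, 0, 1)
#   6. NIR term FN^c = delta * N * D * I^c / (I^r + I^g + I^b), which is
#      proportional to I^c and therefore hue- and saturation-preserving
#   7. fusion F = clip(FN + I (1 - w) + R' w, 0, 1) with weight w = t * VI'

#' Fusion parameters
#'
#' @param delta NIR affectation in \[0, 1\]: how much NIR information is
#'   added by the FN term. Default 0.5.
#' @param omega Enhancement strength in \[0, 1): larger omega gives a smaller
#'   transmission and hence stronger amplification of the inverted image.
#'   Default 0.6.
#' @param t_floor Lower clamp for the transmission map in (0, 1\]; prevents
#'   unbounded amplification. Default 0.1.
#' @param light_percentile Fraction of lowest-vegetation-index pixels used to
#'   estimate the atmospheric light. Default 0.001 (0.1%).
#' @param eps Division guard. Default 1e-6.
#' @param t_formula `"literal"` uses `t = (1 - omega) * D`; `"canonical"`
#'   uses the classical dark-channel-prior form `t = 1 - omega * D`.
#' @param dark_source `"original"` (default) computes the dark channel on
#'   the input VIS image normalized by L, `D = min_c I^c / L^c`;
#'   `"complement"` computes it on the inverted image instead. The default
#'   keeps D at or below ~1 (so the transmission actually varies) and, when
#'   the sky saturates (L close to 1), reduces the enhancement to the
#'   classical divide-by-transmission brightening of the inverted-domain
#'   low-light scheme.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(delta = 0.5, omega = 0.6, t_floor = 0.1,
                          light_percentile = 0.001, eps = 1e-6,
                          t_formula = c("literal", "canonical"),
                          dark_source = c("original", "complement")) {
  t_formula <- match.arg(t_formula)
  dark_source <- match.arg(dark_source)
  stopifnot(
    is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1,
    is.numeric(omega), length(omega) == 1, omega >= 0, omega < 1,
    is.numeric(t_floor), length(t_floor) == 1, t_floor > 0, t_floor <= 1,
    is.numeric(light_percentile), light_percentile > 0, light_percentile <= 1,
    is.numeric(eps), eps > 0
  )
  structure(
    list(delta = delta, omega = omega, t_floor = t_floor,
         light_percentile = light_percentile, eps = eps,
         t_formula = t_formula, dark_source = dark_source),
    class = "fusion_params"
  )
}

#' @export
print.fusion_params <- function(x, ...) {
  cat("<fusion_params> delta=", x$delta, " omega=", x$omega,
      " t_floor=", x$t_floor, " light_percentile=", x$light_percentile,
      " t_formula=", x$t_formula, " dark_source=", x$dark_source, "\n",
      sep = "")
  invisible(x)
}

#' Vegetation index (NDVI) map and its complement
#'
#' `VI = (N - R) / (N + R)` from the NIR plane and the red channel of the
#' VIS image; pixels where `N + R` is below `eps` get VI = 0. The complement
#' weight is `VI' = 1 - clip(VI, 0, 1)`, so negative VI (water, snow,
#' clouds) counts as maximally non-vegetation.
#'
#' @param pair A [registered_pair()].
#' @param eps Guard for the zero-reflectance denominator.
#' @return An object of class `vegetation_map`: list with `vi` (H x W in
#'   \[-1, 1\]) and `vi_comp` (H x W in \[0, 1\]).
#' @export
vegetation_index <- function(pair, eps = 1e-6) {
  stopifnot(inherits(pair, "registered_pair"))
  n <- pair$nir
  r <- pair$vis[, , 1]
  denom <- n + r
  vi <- ifelse(denom < eps, 0, (n - r) / pmax(denom, eps))
  vi <- pmin(pmax(vi, -1), 1)
  structure(list(vi = vi, vi_comp = 1 - pmin(pmax(vi, 0), 1)),
            class = "vegetation_map")
}

#' Image complement (intensity inversion)
#'
#' The normalized equivalent of subtracting each pixel from the maximum
#' representable value: `1 - I` per channel. An involution.
#'
#' @param img Numeric array or matrix in \[0, 1\].
#' @return Same shape, `1 - img`.
#' @export
complement_image <- function(img) {
  stopifnot(all(is.finite(img)), min(img) >= 0, max(img) <= 1)
  1 - img
}

#' Atmospheric light from the least-vegetated pixels
#'
#' Selects the `K = max(1, ceiling(light_percentile * H * W))` pixels with
#' the lowest vegetation index (ties broken by row-major scan order) and
#' takes, independently per channel, the maximum VIS intensity over them.
#' Restricting the search to non-vegetation pixels finds the sky/tarpaulin
#' illumination even when the canopy contains bright specular leaves.
#'
#' @param pair A [registered_pair()].
#' @param vmap A `vegetation_map` from [vegetation_index()].
#' @param params A [fusion_params()].
#' @return Numeric length-3 vector L (one value per channel), floored at
#'   `params$eps`.
#' @export
atmospheric_light <- function(pair, vmap, params = fusion_params()) {
  stopifnot(inherits(pair, "registered_pair"), inherits(vmap, "vegetation_map"))
  h <- nrow(vmap$vi); w <- ncol(vmap$vi)
  k <- max(1L, ceiling(params$light_percentile * h * w))
  # row-major flattening: pixel (i, j) gets index (i-1)*w + j
  vi_rm <- as.vector(t(vmap$vi))
  sel_rm <- order(vi_rm)[seq_len(k)]       # stable: ties in scan order
  rows <- (sel_rm - 1L) %/% w + 1L
  cols <- (sel_rm - 1L) %% w + 1L
  L <- vapply(1:3, function(c) max(pair$vis[cbind(rows, cols, c)]), numeric(1))
  pmax(L, params$eps)
}

#' Transmission map from the dark channel
#'
#' The dark channel is the per-pixel minimum over channels of the image
#' normalized by the atmospheric light, `D(p) = min_c img^c(p) / L^c`
#' (`img` is the original VIS image under the default `dark_source`). The
#' transmission is `t = (1 - omega) * D` (literal form) or `t = 1 - omega * D`
#' (canonical form), clamped to `[t_floor, 1]`; it is a per-pixel scalar
#' broadcast across channels downstream.
#'
#' @param img H x W x 3 array: the original VIS image (default pipeline) or
#'   its complement, per `params$dark_source`.
#' @param light Length-3 atmospheric light from [atmospheric_light()].
#' @param params A [fusion_params()].
#' @return An object of class `transmission_map`: list with `t` (H x W in
#'   \[t_floor, 1\]), `dark` (H x W, unclamped, >= 0) and `light`.
#' @export
transmission_map <- function(img, light, params = fusion_params()) {
  stopifnot(length(light) == 3, all(light > 0))
  dark <- pmin(img[, , 1] / light[1], img[, , 2] / light[2],
               img[, , 3] / light[3])
  t_raw <- if (params$t_formula == "literal") {
    (1 - params$omega) * dark
  } else {
    1 - params$omega * dark
  }
  structure(
    list(t = pmin(pmax(t_raw, params$t_floor), 1), dark = dark, light = light),
    class = "transmission_map"
  )
}

#' Low-light enhancement of the complement image
#'
#' Applies the dehazing-style update `R = L + (I' - L) / t` per channel with
#' the per-pixel transmission, then re-inverts: `R' = 1 - clip(R, 0, 1)`.
#' The inversion brings the enhanced image back to normal polarity (the
#' enhancement operates on the inverted low-light image, where underexposed
#' regions look like haze). With `t = 1` everywhere the update is the
#' identity, so `R' = I`.
#'
#' @param comp H x W x 3 complement image.
#' @param light Length-3 atmospheric light.
#' @param tmap A `transmission_map`.
#' @return List with `raw` (R before clipping; diagnostics) and `enhanced`
#'   (R', in \[0, 1\]).
#' @export
enhance_image <- function(comp, light, tmap) {
  d <- dim(comp)
  raw <- comp
  for (c in 1:3) {
    raw[, , c] <- light[c] + (comp[, , c] - light[c]) / tmap$t
  }
  enhanced <- 1 - pmin(pmax(raw, 0), 1)
  list(raw = raw, enhanced = enhanced)
}

#' Colour-ratio-preserving NIR term
#'
#' `FN^c = delta * N * D * I^c / (I^r + I^g + I^b + eps)`. Because FN is
#' proportional to the pixel's own channel value, adding it scales the RGB
#' vector and leaves hue and HSI saturation unchanged; the dark channel D
#' concentrates the addition on underexposed pixels.
#'
#' @param pair A [registered_pair()].
#' @param dark H x W dark-channel map (unclamped).
#' @param params A [fusion_params()].
#' @return H x W x 3 array, nonnegative.
#' @export
nir_term <- function(pair, dark, params = fusion_params()) {
  vis <- pair$vis
  sum_rgb <- vis[, , 1] + vis[, , 2] + vis[, , 3]
  base <- params$delta * pair$nir * dark / (sum_rgb + params$eps)
  fn <- vis
  for (c in 1:3) fn[, , c] <- base * vis[, , c]
  fn
}

#' Fuse a registered VIS/NIR pair
#'
#' Runs the full pipeline: vegetation index, complement, atmospheric light,
#' transmission map, enhancement and NIR term, then blends
#' `F = clip(FN + I * (1 - w) + R' * w, 0, 1)` with per-pixel weight
#' `w = t * VI'`. The enhanced image enters only where both the transmission
#' and the non-vegetation complement weight allow it, which protects
#' well-exposed sky from over-enhancement while the NIR term brightens the
#' vegetation. Deterministic.
#'
#' @param pair A [registered_pair()].
#' @param params A [fusion_params()].
#' @return An object of class `fusion_result`: list with `fused`, `enhanced`
#'   (R'), `nir_term` (FN), `weights` (w = t * VI'), `fused_raw` (pre-clip),
#'   `vmap`, `tmap`, `light`, `params`, `pair`.
#' @examples
#' sc <- generate_scene(scene_spec(seed = 1, exposure = 0.25))
#' fr <- fuse_pair(sc$pair)
#' tidy(fr)
#' @export
fuse_pair <- function(pair, params = fusion_params()) {
  stopifnot(inherits(pair, "registered_pair"), inherits(params, "fusion_params"))
  vmap <- vegetation_index(pair, eps = params$eps)
  comp <- complement_image(pair$vis)
  light <- atmospheric_light(pair, vmap, params)
  dark_input <- if (params$dark_source == "original") pair$vis else comp
  tmap <- transmission_map(dark_input, light, params)
  enh <- enhance_image(comp, light, tmap)
  fn <- nir_term(pair, tmap$dark, params)

  w <- tmap$t * vmap$vi_comp
  fused_raw <- fn
  for (c in 1:3) {
    fused_raw[, , c] <- fn[, , c] +
      pair$vis[, , c] * (1 - w) + enh$enhanced[, , c] * w
  }
  structure(
    list(fused = pmin(pmax(fused_raw, 0), 1),
         enhanced = enh$enhanced, nir_term = fn, weights = w,
         fused_raw = fused_raw, vmap = vmap, tmap = tmap, light = light,
         params = params, pair = pair),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused)
  cat("<fusion_result> ", d[1], "x", d[2], ", delta=", x$params$delta,
      ", omega=", x$params$omega, "\n", sep = "")
  cat("  atmospheric light L = (", paste(signif(x$light, 4), collapse = ", "),
      ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy a fusion result into per-image quality metrics
#'
#' One row per image role (`original`, `enhanced`, `fused`) with the four
#' quality metrics, ready for plotting or binding across scenes.
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return A tibble with columns `image`, `contrast`, `entropy`,
#'   `colorfulness`, `saturation`.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  dplyr::bind_rows(
    metric_report(x$pair$vis, "original"),
    metric_report(x$enhanced, "enhanced"),
    metric_report(x$fused, "fused")
  ) |>
    dplyr::rename(image = "image_id")
}

#' One-row summary of a fusion result
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return A tibble with the parameter values, the atmospheric light, the
#'   mean transmission and the contrast/saturation change from original to
#'   fused.
#' @method glance fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  orig <- metric_report(x$pair$vis, "original")
  fus <- metric_report(x$fused, "fused")
  tibble::tibble(
    delta = x$params$delta, omega = x$params$omega,
    light_r = x$light[1], light_g = x$light[2], light_b = x$light[3],
    mean_transmission = mean(x$tmap$t),
    contrast_gain = fus$contrast - orig$contrast,
    saturation_shift = fus$saturation - orig$saturation,
    entropy_shift = fus$entropy - orig$entropy,
    colorfulness_gain = fus$colorfulness - orig$colorfulness
  )
}

#' Plot a fusion result
#'
#' Shows the original, enhanced and fused images side by side (as raster
#' panels), or one of the diagnostic maps.
#'
#' @param object A `fusion_result`.
#' @param what `"images"` (original/enhanced/fused), `"weights"`,
#'   `"transmission"` or `"vi"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object,
                                   what = c("images", "weights",
                                            "transmission", "vi"),
                                   ...) {
  what <- match.arg(what)
  if (what == "images") {
    imgs <- list(original = object$pair$vis, enhanced = object$enhanced,
                 fused = object$fused)
    df <- purrr::imap(imgs, function(im, nm) {
      d <- dim(im)
      tibble::tibble(
        panel = nm,
        x = rep(seq_len(d[2]), each = d[1]),
        y = rep(rev(seq_len(d[1])), d[2]),
        fill = grDevices::rgb(im[, , 1], im[, , 2], im[, , 3])
      )
    }) |> purrr::list_rbind()
    df$panel <- factor(df$panel, levels = names(imgs))
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity() +
      ggplot2::facet_wrap(~panel) +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::theme_void()
  } else {
    m <- switch(what, weights = object$weights, transmission = object$tmap$t,
                vi = object$vmap$vi)
    d <- dim(m)
    df <- tibble::tibble(
      x = rep(seq_len(d[2]), each = d[1]),
      y = rep(rev(seq_len(d[1])), d[2]),
      value = as.vector(m)
    )
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::coord_fixed(expand = FALSE) +
      ggplot2::labs(fill = what) +
      ggplot2::theme_void()
    if (what == "vi") {
      # conventional dark-to-green NDVI false colour over [-1, 1]
      p + ggplot2::scale_fill_gradient(low = "black", high = "green3",
                                       limits = c(-1, 1))
    } else {
      p + ggplot2::scale_fill_gradient(low = "black", high = "white",
                                       limits = c(0, 1))
    }
  }
}

#' Write fusion outputs to disk
#'
#' Writes the fused image (8-bit PNG or 16-bit TIFF by extension) and,
#' optionally, the diagnostic maps: vegetation index in the conventional
#' dark-to-green false colour, transmission map and weight map as grayscale
#' PNGs alongside the output.
#'
#' @param result A `fusion_result`.
#' @param path Output image path.
#' @param debug_maps Write `*_vi.png`, `*_t.png`, `*_w.png` next to `path`?
#' @param bits Bit depth for TIFF output.
#' @return `path`, invisibly.
#' @export
write_fusion <- function(result, path, debug_maps = FALSE, bits = 8L) {
  write_image(result$fused, path, bits = bits)
  if (debug_maps) {
    stem <- tools::file_path_sans_ext(path)
    vi01 <- (result$vmap$vi + 1) / 2
    d <- dim(vi01)
    vi_rgb <- array(0, dim = c(d[1], d[2], 3))
    vi_rgb[, , 2] <- vi01                     # dark-to-green ramp
    write_image(vi_rgb, paste0(stem, "_vi.png"))
    write_image(result$tmap$t, paste0(stem, "_t.png"))
    write_image(result$weights, paste0(stem, "_w.png"))
  }
  invisible(path)
}
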