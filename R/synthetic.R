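# Synthetic greenhouse scenes: registered VIS/NIR pairs with ground-truth
# class masks and ripeness-labelled bounding boxes.
#
# The generator encodes only the ordinal structure the fusion method
# exploits, not photorealism: a bright low-vegetation sky/tarpaulin band
# whose NIR reflectance tracks its red channel (VI ~ 0), green foliage with
# high NIR reflectance (VI > 0.2), brown stems, and berry clusters whose
# VIS reflectance depends on ripeness (ripe: near-black; nearly ripe: dark
# with orange patches; unripe: green/orange). Global exposure scales both
# the VIS and the NIR image - ambient illumination hits both sensors, and
# the vegetation index, a ratio of co-scaled bands, stays
# exposure-invariant as it does in the field.

# reflectance palette: VIS rgb + NIR, chosen once so the NDVI semantics
# hold (leaf VI ~ 0.7, sky VI ~ 0, stem VI ~ 0.34)
.palette <- list(
  sky = list(rgb = c(0.92, 0.90, 0.86), nir = NA),   # NIR copies red channel
  leaf = list(rgb = c(0.15, 0.45, 0.10), nir = 0.85),
  stem = list(rgb = c(0.32, 0.24, 0.14), nir = 0.65),
  ripe = list(rgb = c(0.06, 0.05, 0.06), nir = 0.35),
  nearly_ripe = list(rgb = c(0.10, 0.07, 0.08), nir = 0.45),
  nearly_ripe_patch = list(rgb = c(0.70, 0.35, 0.10), nir = 0.85),
  unripe_green = list(rgb = c(0.25, 0.45, 0.15), nir = 0.60),
  unripe_orange = list(rgb = c(0.75, 0.40, 0.10), nir = 0.88)
)

.mask_levels <- c("sky", "leaf", "stem", "fruit")

#' Specification of a synthetic greenhouse scene
#'
#' @param height,width Canvas size in pixels, at least 64. Default 128.
#' @param exposure Global illumination scale in (0, 1\]; values at or below
#'   roughly 0.3 produce underexposed scenes (mean CIELAB L below 40).
#' @param fruit_count Number of berry clusters to place. Default 6.
#' @param ripeness_mix Named proportions over `unripe`, `nearly_ripe`,
#'   `ripe`; must sum to 1.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise
#'   (applied to both VIS and NIR after exposure scaling). Default 0.01.
#' @param seed Integer seed; scenes are deterministic given the spec.
#' @param sky_frac Fraction of the canvas height occupied by the
#'   sky/tarpaulin band. Default 0.3.
#' @param sky_gain Radiance of the directly-illuminated sky/tarpaulin
#'   relative to the diffuse-canopy white point; the sensor clips at 1, so
#'   at normal exposure the ceiling saturates (as the translucent light
#'   source of a real greenhouse does) and stays comparatively bright in
#'   underexposed shots. Default 3.5.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 128, width = 128, exposure = 1,
                       fruit_count = 6,
                       ripeness_mix = c(unripe = 1 / 3, nearly_ripe = 1 / 3,
                                        ripe = 1 / 3),
                       noise_sigma = 0.01, seed = 1, sky_frac = 0.3,
                       sky_gain = 3.5) {
  stopifnot(height >= 64, width >= 64, exposure > 0, exposure <= 1,
            fruit_count >= 0, noise_sigma >= 0,
            sky_frac > 0, sky_frac < 1, sky_gain >= 1)
  if (is.null(names(ripeness_mix))) {
    names(ripeness_mix) <- c("unripe", "nearly_ripe", "ripe")
  }
  stopifnot(setequal(names(ripeness_mix), c("unripe", "nearly_ripe", "ripe")),
            abs(sum(ripeness_mix) - 1) < 1e-8, all(ripeness_mix >= 0))
  structure(
    list(height = as.integer(height), width = as.integer(width),
         exposure = exposure, fruit_count = as.integer(fruit_count),
         ripeness_mix = ripeness_mix[c("unripe", "nearly_ripe", "ripe")],
         noise_sigma = noise_sigma, seed = as.integer(seed),
         sky_frac = sky_frac, sky_gain = sky_gain),
    class = "scene_spec"
  )
}

# run expr with a private RNG stream seeded by `seed`
with_scene_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic registered VIS/NIR scene
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' image pair and the ground truth. The VIS and NIR images are scene
#' radiance scaled by `exposure` and clipped at the sensor white point;
#' because the tarpaulin radiance carries headroom (`sky_gain`), it stays
#' relatively bright in underexposed scenes while the canopy darkens
#' proportionally. Ground truth: a class mask over
#' sky/leaf/stem/fruit and one center-based bounding box
#' `{x, y, w, h, ripeness}` per berry cluster. Deterministic given the spec
#' (including its seed). Geometry depends only on the seed, so two specs
#' differing only in `exposure` produce pixel-aligned scenes.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene`: list with `pair`
#'   (a [registered_pair()]), `truth` (list with `mask`, an H x W factor
#'   matrix-coded integer array with levels sky/leaf/stem/fruit, and
#'   `boxes`, a tibble of center-based boxes), and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(seed = 42, exposure = 0.2))
#' table(mask_labels(sc$truth$mask))
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  max_fruit <- floor((h * (1 - spec$sky_frac) * w) / (24 * 24))
  if (spec$fruit_count > max_fruit) {
    stop("infeasible fruit_count ", spec$fruit_count, " for a ", h, "x", w,
         " canvas (at most ", max_fruit, ")", call. = FALSE)
  }
  with_scene_rng(spec$seed, {
    vis <- array(0, dim = c(h, w, 3))
    nir <- matrix(0, h, w)
    mask <- matrix(2L, h, w)                       # leaf background

    # --- sky/tarpaulin band with a gently wavy lower boundary
    sky_base <- round(spec$sky_frac * h)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 1, 0.04 * h)
    boundary <- pmax(4, pmin(h - 4, round(
      sky_base + amp * sin(2 * pi * seq_len(w) / w + phase))))
    for (j in seq_len(w)) mask[seq_len(boundary[j]), j] <- 1L

    # --- per-pixel reflectance textures (multiplicative, smooth-ish)
    tex <- function(lo, hi) matrix(runif(h * w, lo, hi), h, w)
    leaf_tex <- tex(0.8, 1.2)
    sky_tex <- tex(0.95, 1.03)

    pal <- .palette
    for (c in 1:3) {
      vis[, , c] <- pal$leaf$rgb[c] * leaf_tex
    }
    nir[] <- pal$leaf$nir * pmin(leaf_tex, 1.1)

    # the tarpaulin is directly illuminated: radiance sky_gain times the
    # canopy white point, clipped later at sensor saturation
    sky_idx <- which(mask == 1L)
    for (c in 1:3) {
      ch <- vis[, , c]
      ch[sky_idx] <- spec$sky_gain * pal$sky$rgb[c] * sky_tex[sky_idx]
      vis[, , c] <- ch
    }
    nir[sky_idx] <- vis[, , 1][sky_idx]            # sky NIR tracks red: VI ~ 0

    # --- stems: thin near-vertical strips through the foliage
    n_stems <- sample(2:4, 1)
    stem_cols <- sort(sample(seq(5, w - 5), n_stems))
    for (s in stem_cols) {
      drift <- cumsum(sample(c(-1L, 0L, 0L, 1L), h, replace = TRUE))
      width_s <- sample(2:3, 1)
      for (i in seq_len(h)) {
        if (i <= boundary[min(max(s, 1), w)]) next
        j0 <- s + drift[i]
        cols <- j0:(j0 + width_s - 1L)
        cols <- cols[cols >= 1 & cols <= w]
        keep <- cols[mask[i, cols] == 2L]
        if (length(keep)) {
          mask[i, keep] <- 3L
          for (c in 1:3) vis[i, keep, c] <- pal$stem$rgb[c] * leaf_tex[i, keep]
          nir[i, keep] <- pal$stem$nir * pmin(leaf_tex[i, keep], 1.1)
        }
      }
    }

    # --- fruits: disjoint drupelet-like disk clusters on the foliage
    ripeness <- sample(names(spec$ripeness_mix), spec$fruit_count,
                       replace = TRUE, prob = spec$ripeness_mix)
    boxes <- vector("list", spec$fruit_count)
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    placed <- 0L
    attempts <- 0L
    while (placed < spec$fruit_count && attempts < 500L * spec$fruit_count) {
      attempts <- attempts + 1L
      radius <- runif(1, 4, max(5, min(h, w) / 16))
      ci <- runif(1, max(boundary) + radius + 3, h - radius - 3)
      cj <- runif(1, radius + 3, w - radius - 3)
      # Poisson-disk-style rejection; the margin keeps not only the pixel
      # clusters but also their axis-aligned bounding boxes disjoint
      if (nrow(centers) &&
          any(sqrt((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2) <
              1.7 * (radii + radius) + 3)) next
      placed <- placed + 1L
      rp <- ripeness[placed]
      fruit_px <- draw_fruit(ci, cj, radius, h, w)
      # drop pixels already claimed (shouldn't happen with disjoint clusters)
      fruit_px <- fruit_px[mask[fruit_px] != 4L]
      mask[fruit_px] <- 4L
      cols_px <- (fruit_px - 1L) %/% h + 1L
      rows_px <- (fruit_px - 1L) %% h + 1L
      col_rgb <- switch(rp,
        ripe = pal$ripe$rgb, nearly_ripe = pal$nearly_ripe$rgb,
        unripe = pal$unripe_green$rgb)
      col_nir <- switch(rp,
        ripe = pal$ripe$nir, nearly_ripe = pal$nearly_ripe$nir,
        unripe = pal$unripe_green$nir)
      shade <- runif(length(fruit_px), 0.85, 1.1)
      for (c in 1:3) {
        ch <- vis[, , c]
        ch[fruit_px] <- col_rgb[c] * shade
        vis[, , c] <- ch
      }
      nir[fruit_px] <- col_nir * shade
      # orange accents for unripe / nearly-ripe berries
      if (rp %in% c("unripe", "nearly_ripe")) {
        patch_frac <- if (rp == "unripe") 0.45 else 0.2
        np <- max(1L, round(patch_frac * length(fruit_px)))
        pidx <- sample(seq_along(fruit_px), np)
        patch_pal <- if (rp == "unripe") pal$unripe_orange else
          pal$nearly_ripe_patch
        for (c in 1:3) {
          ch <- vis[, , c]
          ch[fruit_px[pidx]] <- patch_pal$rgb[c] * shade[pidx]
          vis[, , c] <- ch
        }
        nir[fruit_px[pidx]] <- patch_pal$nir * shade[pidx]
      }
      centers <- rbind(centers, c(ci, cj))
      radii <- c(radii, radius)
      x0 <- min(cols_px); x1 <- max(cols_px)
      y0 <- min(rows_px); y1 <- max(rows_px)
      boxes[[placed]] <- tibble::tibble(
        x = (x0 + x1) / 2, y = (y0 + y1) / 2,
        w = x1 - x0 + 1L, h = y1 - y0 + 1L, ripeness = rp)
    }
    if (placed < spec$fruit_count) {
      stop("infeasible fruit_count: could not place ", spec$fruit_count,
           " disjoint clusters", call. = FALSE)
    }
    boxes <- if (placed) purrr::list_rbind(boxes) else
      tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                     h = numeric(), ripeness = character())

    # --- exposure, sensor saturation, then sensor noise, then clip
    vis <- pmin(vis * spec$exposure, 1)
    nir <- pmin(nir * spec$exposure, 1)
    if (spec$noise_sigma > 0) {
      vis <- vis + array(rnorm(length(vis), 0, spec$noise_sigma), dim = dim(vis))
      nir <- nir + matrix(rnorm(length(nir), 0, spec$noise_sigma), h, w)
    }
    vis <- pmin(pmax(vis, 0), 1)
    nir <- pmin(pmax(nir, 0), 1)

    structure(
      list(pair = registered_pair(vis, nir),
           truth = list(mask = mask, boxes = boxes),
           spec = spec),
      class = "scene"
    )
  })
}

# pixel indices (column-major, into an h x w matrix) of one berry cluster:
# overlapping small disks around the centre for a drupelet look
draw_fruit <- function(ci, cj, radius, h, w) {
  n_drupelets <- sample(5:9, 1)
  ang <- runif(n_drupelets, 0, 2 * pi)
  rad <- runif(n_drupelets, 0, radius * 0.55)
  dci <- ci + rad * sin(ang)
  dcj <- cj + rad * cos(ang)
  dr <- runif(n_drupelets, radius * 0.35, radius * 0.6)
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (ii - ci)^2 + (jj - cj)^2 <= radius^2   # main body
  for (k in seq_len(n_drupelets)) {
    inside <- inside | ((ii - dci[k])^2 + (jj - dcj[k])^2 <= dr[k]^2)
  }
  inside[, c(1, w)] <- FALSE
  inside[c(1, h), ] <- FALSE
  which(inside)
}

#' Class labels of a truth mask
#'
#' @param mask Integer H x W matrix as stored in `scene$truth$mask`.
#' @return Character matrix-shaped vector with levels sky/leaf/stem/fruit.
#' @export
mask_labels <- function(mask) {
  m <- .mask_levels[mask]
  dim(m) <- dim(mask)
  m
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", x$spec$height, "x", x$spec$width, ", exposure ",
      x$spec$exposure, ", ", nrow(x$truth$boxes), " fruits, seed ",
      x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_scenes` registered pairs (8-bit PNG), truth masks (indexed
#' grayscale PNG with codes 1-4 for sky/leaf/stem/fruit), bounding boxes
#' (JSON lines with the center-based `{x, y, w, h, ripeness}` record) and a
#' manifest CSV listing them. Per-scene seeds are derived deterministically
#' from the master seed, so the same call reproduces the dataset
#' byte-for-byte.
#'
#' @param n_scenes Number of scenes.
#' @param dir Output directory (created if missing).
#' @param spec_template A [scene_spec()] supplying every field except the
#'   seed.
#' @param seed Master seed.
#' @return Tibble manifest (also written to `dir/manifest.csv`) with columns
#'   `scene_id`, `vis`, `nir`, `mask`, `boxes`, `seed`, `exposure`.
#' @export
generate_dataset <- function(n_scenes, dir, spec_template = scene_spec(),
                             seed = 1) {
  stopifnot(n_scenes >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(seq_len(n_scenes), function(i) {
    scene_seed <- (seed + 104729L * i) %% 2147483647L
    sp <- spec_template
    sp$seed <- as.integer(scene_seed)
    sc <- generate_scene(sp)
    id <- sprintf("scene_%03d", i)
    vis_p <- file.path(dir, paste0(id, "_vis.png"))
    nir_p <- file.path(dir, paste0(id, "_nir.png"))
    mask_p <- file.path(dir, paste0(id, "_mask.png"))
    box_p <- file.path(dir, paste0(id, "_boxes.jsonl"))
    write_image(sc$pair$vis, vis_p)
    write_image(sc$pair$nir, nir_p)
    write_image(sc$truth$mask / 255, mask_p)     # codes 1..4 as gray levels
    writeLines(
      vapply(seq_len(nrow(sc$truth$boxes)), function(b) {
        jsonlite::toJSON(as.list(sc$truth$boxes[b, ]), auto_unbox = TRUE)
      }, character(1)),
      box_p)
    tibble::tibble(scene_id = id, vis = vis_p, nir = nir_p, mask = mask_p,
                   boxes = box_p, seed = scene_seed,
                   exposure = sp$exposure)
  }) |> purrr::list_rbind()
  readr::write_csv(rows, file.path(dir, "manifest.csv"))
  rows
}

#' Read a truth mask written by [generate_dataset()]
#'
#' @param path Mask PNG path.
#' @return Integer H x W matrix with codes 1-4 (sky/leaf/stem/fruit).
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read a boxes JSON-lines file written by [generate_dataset()]
#'
#' @param path `.jsonl` path.
#' @return Tibble with columns `x`, `y`, `w`, `h`, `ripeness`.
#' @export
read_boxes <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                          h = numeric(), ripeness = character()))
  }
  purrr::map(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }) |> purrr::list_rbind()
}
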