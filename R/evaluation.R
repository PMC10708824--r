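# Experimental bookkeeping: exposure split by mean CIELAB lightness,
# ripeness patch extraction and augmentation, and batch metric tables with
# Tukey all-pairs comparisons across fusion methods.

#' Classify an image as underexposed or normally exposed
#'
#' Computes the mean of the CIELAB L plane (0-100 scale) and labels the
#' image `low` when it falls strictly below the threshold, `normal`
#' otherwise. The split is monotone in global exposure: darkening an image
#' can only move it towards `low`.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @param threshold Mean-lightness cutoff, default 40.
#' @param image_id Identifier carried into the output.
#' @return One-row tibble with `image_id`, `mean_L`, `label`.
#' @export
exposure_split <- function(vis, threshold = 40, image_id = "image") {
  mean_L <- mean(to_lab(vis)$L)
  tibble::tibble(
    image_id = image_id,
    mean_L = mean_L,
    label = ifelse(mean_L < threshold, "low", "normal")
  )
}

#' Extract ripeness-labelled patches from bounding boxes
#'
#' Converts each center-based box `{x, y, w, h}` to a pixel window, crops
#' it (clipped to the image bounds), and resizes the crop to
#' `size` x `size` with bilinear interpolation. Optionally samples
#' background windows from box-free regions and labels them `no_fruit`.
#' Degenerate boxes (width or height below 2 px after clipping) are skipped
#' with a warning.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @param boxes Tibble with columns `x`, `y`, `w`, `h` (center-based) and
#'   `ripeness`.
#' @param size Output patch side length, default 224.
#' @param n_background Number of `no_fruit` background patches to sample
#'   from regions that intersect no box. Default 0.
#' @param seed Seed for background sampling.
#' @param image_id Identifier carried into the records.
#' @return Tibble of patch records: `image_id`, `x`, `y`, `w`, `h`,
#'   `ripeness`, and `patch` (list-column of `size` x `size` x 3 arrays).
#' @export
extract_patches <- function(vis, boxes, size = 224, n_background = 0,
                            seed = 1, image_id = "image") {
  vis <- validate_rgb(vis)
  H <- dim(vis)[1]; W <- dim(vis)[2]
  crop_one <- function(x, y, w, h, label) {
    x0 <- max(1L, round(x - (w - 1) / 2)); x1 <- min(W, x0 + round(w) - 1L)
    y0 <- max(1L, round(y - (h - 1) / 2)); y1 <- min(H, y0 + round(h) - 1L)
    if (x1 - x0 + 1 < 2 || y1 - y0 + 1 < 2) {
      warning("skipping degenerate box at (", x, ", ", y, ")", call. = FALSE)
      return(NULL)
    }
    crop <- vis[y0:y1, x0:x1, , drop = FALSE]
    tibble::tibble(image_id = image_id, x = x, y = y, w = w, h = h,
                   ripeness = label,
                   patch = list(resize_bilinear(crop, size, size)))
  }
  records <- purrr::pmap(
    list(boxes$x, boxes$y, boxes$w, boxes$h, boxes$ripeness),
    crop_one
  ) |> purrr::compact() |> purrr::list_rbind()

  if (n_background > 0) {
    bg <- with_scene_rng(seed, {
      side <- if (nrow(boxes)) round(stats::median(c(boxes$w, boxes$h)))
              else round(min(H, W) / 4)
      side <- max(8, min(side, min(H, W) - 1))
      out <- list()
      attempts <- 0L
      while (length(out) < n_background && attempts < 200L * n_background) {
        attempts <- attempts + 1L
        cx <- runif(1, side / 2 + 1, W - side / 2)
        cy <- runif(1, side / 2 + 1, H - side / 2)
        # reject windows overlapping any annotated box
        if (nrow(boxes)) {
          dx <- abs(boxes$x - cx); dy <- abs(boxes$y - cy)
          if (any(dx < (boxes$w + side) / 2 & dy < (boxes$h + side) / 2)) next
        }
        out[[length(out) + 1L]] <- crop_one(cx, cy, side, side, "no_fruit")
      }
      purrr::list_rbind(out)
    })
    records <- dplyr::bind_rows(records, bg)
  }
  if (is.null(records)) {
    records <- tibble::tibble(image_id = character(), x = numeric(),
                              y = numeric(), w = numeric(), h = numeric(),
                              ripeness = character(), patch = list())
  }
  records
}

#' Write patches into class-named directories
#'
#' The conventional image-classification layout: one directory per ripeness
#' label, PNG files inside.
#'
#' @param records Tibble from [extract_patches()].
#' @param dir Output root directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_patches <- function(records, dir) {
  paths <- purrr::map_chr(seq_len(nrow(records)), function(i) {
    cls_dir <- file.path(dir, records$ripeness[i])
    dir.create(cls_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(cls_dir, sprintf("%s_%03d.png", records$image_id[i], i))
    write_image(records$patch[[i]], p)
    p
  })
  invisible(paths)
}

#' Randomly augment a patch
#'
#' Applies, in order, a horizontal reflection (probability 0.5), a rotation
#' uniform in \[-180, 180\] degrees, a translation uniform in \[-15, 15\] px
#' on each axis, and a horizontal shear uniform in \[-10, 10\] px (the
#' lateral displacement reached at the top/bottom edge). Transforms are
#' composed about the patch centre into a single affine map and applied in
#' one bilinear resample with reflected border padding, so the output keeps
#' the input's size and value range. Any parameter given explicitly
#' overrides its random draw; with `flip = FALSE` and the numeric
#' parameters 0 the output equals the input.
#'
#' @param patch H x W x 3 array (typically 224 x 224 x 3).
#' @param seed Seed for the random draws (ignored for parameters supplied
#'   explicitly).
#' @param flip Logical; mirror horizontally?
#' @param angle Rotation in degrees.
#' @param dx,dy Translation in pixels.
#' @param shear Horizontal shear in pixels.
#' @return Augmented patch, same dimensions.
#' @export
augment_patch <- function(patch, seed = 1, flip = NULL, angle = NULL,
                          dx = NULL, dy = NULL, shear = NULL) {
  patch <- validate_rgb(patch)
  draws <- with_scene_rng(seed, list(
    flip = runif(1) < 0.5,
    angle = runif(1, -180, 180),
    dx = runif(1, -15, 15),
    dy = runif(1, -15, 15),
    shear = runif(1, -10, 10)
  ))
  if (is.null(flip)) flip <- draws$flip
  if (is.null(angle)) angle <- draws$angle
  if (is.null(dx)) dx <- draws$dx
  if (is.null(dy)) dy <- draws$dy
  if (is.null(shear)) shear <- draws$shear

  h <- dim(patch)[1]; w <- dim(patch)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  mat <- function(a, b, c, d, e, f) {
    matrix(c(a, b, c, d, e, f, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  Tc <- mat(1, 0, -cx, 0, 1, -cy)     # to centre
  Tb <- mat(1, 0, cx, 0, 1, cy)       # back
  Fm <- if (flip) Tb %*% mat(-1, 0, 0, 0, 1, 0) %*% Tc else diag(3)
  cs <- cospi(angle / 180); sn <- sinpi(angle / 180)
  Rm <- Tb %*% mat(cs, -sn, 0, sn, cs, 0) %*% Tc
  Tm <- mat(1, 0, dx, 0, 1, dy)
  k <- shear / ((h - 1) / 2)          # px of x-offset reached at the edge
  Sm <- Tb %*% mat(1, k, 0, 0, 1, 0) %*% Tc
  fwd <- Sm %*% Tm %*% Rm %*% Fm      # reflect -> rotate -> translate -> shear
  warp_affine(patch, solve(fwd), h, w)
}

#' Compare fusion methods on a dataset with paired quality metrics
#'
#' Runs each method over every registered pair, computes the four quality
#' metrics per fused image, and performs, per metric, an all-pairs
#' comparison of method means with Tukey's honest significant difference at
#' the given alpha (via `stats::aov` + `stats::TukeyHSD`). A method that
#' fails on an image is recorded as missing for that image and the run
#' continues.
#'
#' @param pairs A list of [registered_pair()] objects, or a manifest tibble
#'   from [generate_dataset()] (columns `vis`, `nir`, `scene_id`).
#' @param methods Named list of functions mapping a `registered_pair` to an
#'   H x W x 3 fused image. Include
#'   `original = function(p) p$vis` to use the unprocessed image as the
#'   baseline.
#' @param alpha Significance level for the Tukey comparisons. Default 0.05.
#' @return An object of class `method_comparison`: list with `metrics`
#'   (tibble: one row per image x method) and `comparisons` (tibble: one row
#'   per metric x method pair, with the mean difference, adjusted p-value
#'   and significance flag).
#' @export
compare_methods <- function(pairs, methods, alpha = 0.05) {
  stopifnot(length(methods) >= 1, !is.null(names(methods)))
  if (is.data.frame(pairs)) {
    ids <- pairs$scene_id
    pairs <- purrr::map2(pairs$vis, pairs$nir, load_pair)
    names(pairs) <- ids
  }
  if (is.null(names(pairs))) {
    names(pairs) <- sprintf("image_%03d", seq_along(pairs))
  }
  metrics <- purrr::imap(pairs, function(pair, id) {
    purrr::imap(methods, function(fn, mname) {
      img <- tryCatch(fn(pair), error = function(e) {
        warning("method '", mname, "' failed on ", id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(img)) {
        tibble::tibble(image_id = id, method = mname, contrast = NA_real_,
                       entropy = NA_real_, colorfulness = NA_real_,
                       saturation = NA_real_)
      } else {
        dplyr::mutate(metric_report(img, id), method = mname,
                      .after = "image_id")
      }
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  long <- tidyr::pivot_longer(metrics, c("contrast", "entropy",
                                         "colorfulness", "saturation"),
                              names_to = "metric", values_to = "value")
  comparisons <- if (length(methods) < 2) {
    tibble::tibble(metric = character(), comparison = character(),
                   difference = numeric(), lwr = numeric(), upr = numeric(),
                   p_adj = numeric(), significant = logical())
  } else {
    long |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::group_by(.data$metric) |>
      dplyr::group_modify(function(d, key) {
        if (dplyr::n_distinct(d$method) < 2) {
          return(tibble::tibble(comparison = character(),
                                difference = numeric(), lwr = numeric(),
                                upr = numeric(), p_adj = numeric(),
                                significant = logical()))
        }
        d$method <- factor(d$method)
        tk <- TukeyHSD(aov(value ~ method, data = d))$method
        tibble::tibble(comparison = rownames(tk), difference = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"],
                       significant = !is.na(tk[, "p adj"]) &
                         tk[, "p adj"] < alpha)
      }) |>
      dplyr::ungroup()
  }
  structure(list(metrics = metrics, comparisons = comparisons, alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> ", dplyr::n_distinct(x$metrics$image_id),
      " images x ", dplyr::n_distinct(x$metrics$method), " methods\n",
      sep = "")
  print(x$comparisons)
  invisible(x)
}

#' Tidy the Tukey comparison table of a method comparison
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return The comparisons tibble (metric, method pair, mean difference,
#'   interval, adjusted p-value, significance).
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) x$comparisons

#' Per-method metric means of a method comparison
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per method and the mean of each metric.
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("contrast", "entropy", "colorfulness",
                                     "saturation"),
                                   ~mean(.x, na.rm = TRUE)),
                     n = dplyr::n(), .groups = "drop")
}

#' Plot metric distributions by method
#'
#' @param object A `method_comparison`.
#' @param ... Unused.
#' @return A ggplot: boxplots of each metric per method.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("contrast", "entropy", "colorfulness",
                                "saturation"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Write a method-comparison to CSV files
#'
#' @param x A `method_comparison`.
#' @param dir Output directory; writes `metrics.csv` and `comparisons.csv`.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(x$comparisons, file.path(dir, "comparisons.csv"))
  invisible(dir)
}
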