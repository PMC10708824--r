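# Fusion-quality metrics: RMS contrast, Shannon entropy, CIELAB
# colorfulness and HSI saturation. All statistics over pixels use the
# population convention (divide by the pixel count), so closed forms for
# two-level images hold exactly.

pop_sd <- function(x) sqrt(mean(x^2) - mean(x)^2)

#' Contrast of a single-channel image
#'
#' Global contrast on the conventional 0-255 intensity scale. The default is
#' RMS contrast, the population standard deviation of intensity,
#' `sqrt(mean(I^2) - mean(I)^2)` with `I = 255 * gray`. `mode = "variance"`
#' returns the raw variance instead (the same expression without the square
#' root), which grows quadratically and is rarely the scale on which contrast
#' differences of a few units are discussed.
#'
#' @param gray H x W matrix in \[0, 1\] (see [to_gray()]), or an H x W x 3
#'   array, which is converted to grayscale first.
#' @param mode `"rms"` (default) or `"variance"`.
#' @return Nonnegative scalar.
#' @examples
#' metric_contrast(matrix(c(0, 1), 2, 2))  # checkerboard of 0 and 255: 127.5
#' @export
metric_contrast <- function(gray, mode = c("rms", "variance")) {
  mode <- match.arg(mode)
  if (is.array(gray) && length(dim(gray)) == 3L) gray <- to_gray(gray)
  if (length(gray) == 0) stop("empty image", call. = FALSE)
  v <- mean((255 * gray)^2) - mean(255 * gray)^2
  v <- max(v, 0)  # guard tiny negative from cancellation
  if (mode == "rms") sqrt(v) else v
}

#' Shannon entropy of an image
#'
#' Per-channel entropy of the 256-bin gray-level histogram,
#' `-sum(P(g) log2 P(g))` with `0 log 0 := 0`, averaged over channels.
#' Bins are uniform over \[0, 1\] with the last bin closed at 1, so 8-bit
#' levels `g/255` land in bin `g`. Bounded by 8 bits.
#'
#' @param img H x W matrix or H x W x 3 array in \[0, 1\].
#' @return Entropy in bits, in \[0, 8\].
#' @export
metric_entropy <- function(img) {
  channel_entropy <- function(x) {
    g <- pmin(floor(as.vector(x) * 256), 255)
    p <- tabulate(g + 1L, nbins = 256L) / length(g)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    mean(vapply(seq_len(dim(img)[3]), function(k) channel_entropy(img[, , k]),
                numeric(1)))
  } else {
    channel_entropy(img)
  }
}

#' CIELAB colorfulness
#'
#' `CF = sd(a) + sd(b) + 0.94 * mean(sqrt(a^2 + b^2))` over all pixels, with
#' a and b the CIELAB chromatic coordinates (red-green and yellow-blue) and
#' population standard deviations. Zero exactly for achromatic images.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @return Nonnegative scalar in CIELAB units.
#' @export
metric_colorfulness <- function(vis) {
  lab <- to_lab(vis)
  pop_sd(lab$a) + pop_sd(lab$b) + 0.94 * mean(sqrt(lab$a^2 + lab$b^2))
}

#' Mean HSI saturation
#'
#' Mean of the HSI saturation plane ([hsi_saturation()]); 0 for grayscale
#' images, 1 for fully saturated pure hues.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
metric_saturation <- function(vis) {
  mean(hsi_saturation(vis))
}

#' Full quality report for one image
#'
#' Computes contrast (on the Rec. 601 grayscale), entropy, colorfulness and
#' saturation, returning them as a one-row tibble so that reports for many
#' images stack with `dplyr::bind_rows()`.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @param image_id Identifier stored alongside the metrics.
#' @param contrast_mode Passed to [metric_contrast()].
#' @return A tibble with columns `image_id`, `contrast`, `entropy`,
#'   `colorfulness`, `saturation`.
#' @export
metric_report <- function(vis, image_id = "image", contrast_mode = "rms") {
  vis <- validate_rgb(vis)
  tibble::tibble(
    image_id = image_id,
    contrast = metric_contrast(to_gray(vis), mode = contrast_mode),
    entropy = metric_entropy(vis),
    colorfulness = metric_colorfulness(vis),
    saturation = metric_saturation(vis)
  )
}

#' Write metric reports to CSV
#'
#' @param reports Tibble of stacked [metric_report()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  readr::write_csv(reports, path)
  invisible(path)
}
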