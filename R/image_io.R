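# Image input/output, bit-depth normalization and colour-space planes.
#
# All images live internally as numeric arrays in [0, 1]: H x W x 3 for
# visible (RGB) images, H x W matrices for single-channel planes (NIR, gray).
# Integer formulas written for 8-bit data are rescaled algebraically to this
# space, so the complement of an image is simply 1 - I.

#' Construct a registered VIS/NIR image pair
#'
#' Bundles an RGB visible-spectrum image and a single-channel near-infrared
#' image of the same scene into a validated pair. The two images must be
#' pixel-registered: identical height and width, both with finite values in
#' \[0, 1\].
#'
#' @param vis Numeric H x W x 3 array, values in \[0, 1\].
#' @param nir Numeric H x W matrix in \[0, 1\]. A H x W x k array whose
#'   channels are identical is collapsed to its first channel.
#' @param bit_depth_src Integer, 8 or 16; the bit depth the data came from.
#' @param source_paths Optional character(2) with the VIS and NIR file paths.
#' @return An object of class `registered_pair`: a list with elements `vis`,
#'   `nir`, `bit_depth_src`, `source_paths`.
#' @examples
#' vis <- array(0.5, dim = c(8, 8, 3))
#' nir <- matrix(0.8, 8, 8)
#' pair <- registered_pair(vis, nir)
#' @export
registered_pair <- function(vis, nir, bit_depth_src = 8L, source_paths = NULL) {
  vis <- validate_rgb(vis, "vis")
  nir <- collapse_nir(nir)
  if (nrow(nir) != dim(vis)[1] || ncol(nir) != dim(vis)[2]) {
    stop("registration error: VIS is ", dim(vis)[1], "x", dim(vis)[2],
         " but NIR is ", nrow(nir), "x", ncol(nir), call. = FALSE)
  }
  if (!all(is.finite(nir)) || min(nir) < 0 || max(nir) > 1) {
    stop("nir must be finite and within [0, 1]", call. = FALSE)
  }
  structure(
    list(vis = vis, nir = nir, bit_depth_src = as.integer(bit_depth_src),
         source_paths = source_paths),
    class = "registered_pair"
  )
}

#' @export
print.registered_pair <- function(x, ...) {
  d <- dim(x$vis)
  cat("<registered_pair> ", d[1], "x", d[2],
      " VIS(3ch) + NIR, ", x$bit_depth_src, "-bit source\n", sep = "")
  invisible(x)
}

validate_rgb <- function(vis, name = "vis") {
  if (is.matrix(vis)) {
    # grayscale promoted to 3 identical channels
    vis <- array(rep(vis, 3L), dim = c(nrow(vis), ncol(vis), 3L))
  }
  if (!is.array(vis) || length(dim(vis)) != 3L || dim(vis)[3] < 3L) {
    stop(name, " must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(vis)[3] > 3L) vis <- vis[, , 1:3, drop = FALSE]  # drop alpha
  if (!all(is.finite(vis)) || min(vis) < 0 || max(vis) > 1) {
    stop(name, " must be finite and within [0, 1]", call. = FALSE)
  }
  vis
}

collapse_nir <- function(nir) {
  if (is.array(nir) && length(dim(nir)) == 3L) {
    nch <- dim(nir)[3]
    if (nch > 1L) {
      base <- nir[, , 1L]
      keep <- if (nch == 4L) 1:3 else seq_len(nch)  # ignore alpha
      for (k in keep[-1L]) {
        if (max(abs(nir[, , k] - base)) > 1 / 255) {
          stop("format error: NIR image has distinct channels; expected ",
               "single-channel or replicated-channel data", call. = FALSE)
        }
      }
    }
    nir <- nir[, , 1L]
  }
  if (!is.matrix(nir)) stop("nir must be an H x W matrix", call. = FALSE)
  nir
}

#' Load a registered VIS/NIR pair from image files
#'
#' Reads a visible RGB image and a near-infrared image (PNG or TIFF, 8- or
#' 16-bit), normalizes intensities to \[0, 1\] by dividing by `2^bits - 1`,
#' and validates that the two are pixel-registered. A NIR file stored as RGB
#' with identical channels is collapsed to one channel.
#'
#' @param vis_path,nir_path Paths to the VIS and NIR image files.
#' @return A [registered_pair()].
#' @export
load_pair <- function(vis_path, nir_path) {
  vis <- read_image(vis_path)
  nir <- read_image(nir_path)
  registered_pair(
    vis = validate_rgb(vis$data, "vis"),
    nir = collapse_nir(nir$data),
    bit_depth_src = max(vis$bits, nir$bits),
    source_paths = c(vis = vis_path, nir = nir_path)
  )
}

# Read PNG or TIFF; returns list(data in [0,1], bits). png/tiff readers
# already divide by the type maximum, so only the bit depth is recovered.
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    data <- png::readPNG(path)
    hdr <- readBin(path, "raw", n = 26L)
    bits <- as.integer(hdr[25])            # IHDR bit-depth byte
    if (!bits %in% c(8L, 16L)) {
      stop("format error: unsupported PNG bit depth ", bits, call. = FALSE)
    }
  } else if (ext %in% c("tif", "tiff")) {
    data <- tiff::readTIFF(path, info = TRUE)
    bits <- as.integer(attr(data, "bits.per.sample"))
    if (length(bits) == 0 || is.na(bits)) bits <- 8L
    if (!bits %in% c(8L, 16L)) {
      stop("format error: unsupported TIFF bit depth ", bits, call. = FALSE)
    }
    attributes(data) <- attributes(data)["dim"]
  } else {
    stop("format error: unsupported extension '", ext, "'", call. = FALSE)
  }
  list(data = data, bits = bits)
}

#' Write an image to PNG (8-bit) or TIFF (8/16-bit)
#'
#' Values are quantized with round-half-up to the target bit depth before
#' writing, so a value `v` maps to integer `floor(v * (2^bits - 1) + 0.5)`.
#'
#' @param img Numeric matrix or H x W x 3 array in \[0, 1\].
#' @param path Output path; format chosen from the extension (.png/.tif/.tiff).
#' @param bits 8 or 16. PNG output is always 8-bit.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  img[] <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    q <- floor(img * 255 + 0.5) / 255
    png::writePNG(q, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    m <- 2^bits - 1
    q <- floor(img * m + 0.5) / m
    tiff::writeTIFF(q, where = path, bits.per.sample = as.integer(bits))
  } else {
    stop("format error: unsupported extension '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Rec. 601 luminance grayscale
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @return H x W matrix, `0.299 R + 0.587 G + 0.114 B`.
#' @export
to_gray <- function(vis) {
  vis <- validate_rgb(vis)
  0.299 * vis[, , 1] + 0.587 * vis[, , 2] + 0.114 * vis[, , 3]
}

#' CIELAB planes of an RGB image
#'
#' Converts through the standard sRGB (D65) transform, i.e. the input is
#' interpreted as gamma-encoded sRGB, matching the conventional `rgb2lab` of
#' mainstream image-processing environments. L is on \[0, 100\].
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @return List with H x W matrices `L`, `a`, `b`.
#' @export
to_lab <- function(vis) {
  vis <- validate_rgb(vis)
  d <- dim(vis)
  rgb <- cbind(as.vector(vis[, , 1]), as.vector(vis[, , 2]), as.vector(vis[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(
    L = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  )
}

#' HSI saturation plane
#'
#' `S = 1 - 3 min(r, g, b) / (r + g + b + eps)`; black pixels get S = 0 by
#' the epsilon guard, the usual convention for the achromatic origin.
#'
#' @param vis H x W x 3 array in \[0, 1\].
#' @param eps Division guard.
#' @return H x W matrix in \[0, 1\].
#' @export
hsi_saturation <- function(vis, eps = 1e-6) {
  vis <- validate_rgb(vis)
  mn <- pmin(vis[, , 1], vis[, , 2], vis[, , 3])
  sm <- vis[, , 1] + vis[, , 2] + vis[, , 3]
  s <- 1 - 3 * mn / (sm + eps)
  s[sm < eps] <- 0
  pmin(pmax(s, 0), 1)
}
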