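# Bilinear affine resampling with reflected border padding. One primitive
# serves both patch resizing and geometric augmentation, so the two share
# interpolation behaviour and tests.

# reflect continuous coordinates into [1, n] (mirror at the borders,
# edge pixels not duplicated)
reflect_coord <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  t <- (x - 1) %% p
  1 + (n - 1) - abs(t - (n - 1))
}

# sample img (H x W matrix) at continuous (rows, cols) with bilinear
# interpolation; coordinates outside the canvas are reflected
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  r <- reflect_coord(rows, h)
  c <- reflect_coord(cols, w)
  r0 <- pmin(pmax(floor(r), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(c), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- r - r0
  fc <- c - c0
  v00 <- img[cbind(r0, c0)]; v01 <- img[cbind(r0, c1)]
  v10 <- img[cbind(r1, c0)]; v11 <- img[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# apply an affine map to an image. `inv` is the 3x3 inverse (output -> source)
# homogeneous matrix acting on (x = col, y = row, 1) coordinates.
warp_affine <- function(img, inv, out_h, out_w) {
  xo <- rep(seq_len(out_w), each = out_h)
  yo <- rep(seq_len(out_h), out_w)
  src <- inv %*% rbind(xo, yo, 1)
  if (is.matrix(img)) {
    matrix(bilinear_sample(img, src[2, ], src[1, ]), out_h, out_w)
  } else {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) {
      out[, , k] <- matrix(bilinear_sample(img[, , k], src[2, ], src[1, ]),
                           out_h, out_w)
    }
    out
  }
}

#' Bilinear image resize
#'
#' Pixel-centre-aligned bilinear resampling with reflected borders; resizing
#' to the input size is the identity.
#'
#' @param img H x W matrix or H x W x C array.
#' @param out_h,out_w Output dimensions.
#' @return Resized image.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  sx <- w / out_w
  sy <- h / out_h
  # output pixel centre (x, y) maps back to source (x - 0.5) * s + 0.5
  inv <- matrix(c(sx, 0, 0.5 - 0.5 * sx,
                  0, sy, 0.5 - 0.5 * sy,
                  0, 0, 1), 3, 3, byrow = TRUE)
  warp_affine(img, inv, out_h, out_w)
}
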