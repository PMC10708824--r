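# Small programmatic fixtures shared across test files.

# random registered pair with controllable size, reproducible
random_pair <- function(h = 12, w = 10, seed = 1) {
  set.seed(seed)
  registered_pair(array(runif(h * w * 3), dim = c(h, w, 3)),
                  matrix(runif(h * w), h, w))
}

# solid-colour RGB image
solid_rgb <- function(rgb, h = 8, w = 8) {
  out <- array(0, dim = c(h, w, 3))
  for (c in 1:3) out[, , c] <- rgb[c]
  out
}

# pair that is "all vegetation" (VI = 1 everywhere: NIR = 1, red = 0),
# so the complement vegetation weight VI' is identically zero
all_vegetation_pair <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  vis <- array(runif(h * w * 3, 0.2, 0.8), dim = c(h, w, 3))
  vis[, , 1] <- 0
  registered_pair(vis, matrix(1, h, w))
}
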