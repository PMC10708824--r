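# Independent per-pixel reference implementations, written as plain scalar
# loops over the defining formulas. They deliberately share no code with
# the vectorized pipeline (the colour transform, delegated to grDevices in
# both, is the one exception).

oracle_contrast <- function(gray, mode = "rms") {
  s <- 0; s2 <- 0; n <- 0
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray))) {
      v <- 255 * gray[i, j]
      s <- s + v; s2 <- s2 + v * v; n <- n + 1
    }
  }
  v <- s2 / n - (s / n)^2
  if (mode == "rms") sqrt(max(v, 0)) else v
}

oracle_entropy <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
  total <- 0
  for (k in seq_len(dim(img)[3])) {
    counts <- numeric(256)
    for (i in seq_len(dim(img)[1])) {
      for (j in seq_len(dim(img)[2])) {
        g <- min(floor(img[i, j, k] * 256), 255)
        counts[g + 1] <- counts[g + 1] + 1
      }
    }
    p <- counts / sum(counts)
    en <- 0
    for (q in p) if (q > 0) en <- en - q * log2(q)
    total <- total + en
  }
  total / dim(img)[3]
}

oracle_colorfulness <- function(vis) {
  h <- dim(vis)[1]; w <- dim(vis)[2]
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      lab <- grDevices::convertColor(matrix(vis[i, j, ], 1), "sRGB", "Lab")
      a[i, j] <- lab[1, 2]; b[i, j] <- lab[1, 3]
    }
  }
  n <- h * w
  sda <- sqrt(sum((a - sum(a) / n)^2) / n)
  sdb <- sqrt(sum((b - sum(b) / n)^2) / n)
  chroma <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    chroma <- chroma + sqrt(a[i, j]^2 + b[i, j]^2)
  }
  sda + sdb + 0.94 * chroma / n
}

oracle_saturation <- function(vis, eps = 1e-6) {
  h <- dim(vis)[1]; w <- dim(vis)[2]
  acc <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- vis[i, j, 1]; g <- vis[i, j, 2]; bb <- vis[i, j, 3]
      s <- r + g + bb
      acc <- acc + if (s < eps) 0 else 1 - 3 * min(r, g, bb) / (s + eps)
    }
  }
  acc / (h * w)
}

# scalar reference for the whole fusion pipeline
oracle_fuse <- function(pair, params = fusion_params()) {
  vis <- pair$vis; nir <- pair$nir
  h <- dim(vis)[1]; w <- dim(vis)[2]
  eps <- params$eps

  vi <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      n <- nir[i, j]; r <- vis[i, j, 1]
      vi[i, j] <- if (n + r < eps) 0 else (n - r) / (n + r)
      vi[i, j] <- max(-1, min(1, vi[i, j]))
    }
  }
  vic <- 1 - pmax(pmin(vi, 1), 0)

  comp <- 1 - vis

  # atmospheric light: K lowest-VI pixels in row-major order, stable ties
  k <- max(1, ceiling(params$light_percentile * h * w))
  flat <- data.frame(idx = seq_len(h * w))
  flat$row <- (flat$idx - 1) %/% w + 1
  flat$col <- (flat$idx - 1) %% w + 1
  flat$vi <- vi[cbind(flat$row, flat$col)]
  flat <- flat[order(flat$vi, flat$idx), ]
  sel <- flat[seq_len(k), ]
  L <- c(0, 0, 0)
  for (c in 1:3) {
    m <- -Inf
    for (q in seq_len(k)) m <- max(m, vis[sel$row[q], sel$col[q], c])
    L[c] <- max(m, eps)
  }

  dark_src <- if (params$dark_source == "original") vis else comp
  dark <- matrix(0, h, w); tmap <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      d <- min(dark_src[i, j, 1] / L[1], dark_src[i, j, 2] / L[2],
               dark_src[i, j, 3] / L[3])
      dark[i, j] <- d
      tr <- if (params$t_formula == "literal") (1 - params$omega) * d
            else 1 - params$omega * d
      tmap[i, j] <- max(params$t_floor, min(1, tr))
    }
  }

  enh <- array(0, dim = dim(vis))
  fn <- array(0, dim = dim(vis))
  fused_raw <- array(0, dim = dim(vis))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      srgb <- vis[i, j, 1] + vis[i, j, 2] + vis[i, j, 3]
      wgt <- tmap[i, j] * vic[i, j]
      for (c in 1:3) {
        R <- L[c] + (comp[i, j, c] - L[c]) / tmap[i, j]
        rp <- 1 - max(0, min(1, R))
        enh[i, j, c] <- rp
        fn[i, j, c] <- params$delta * nir[i, j] * dark[i, j] *
          vis[i, j, c] / (srgb + eps)
        fused_raw[i, j, c] <- fn[i, j, c] +
          vis[i, j, c] * (1 - wgt) + rp * wgt
      }
    }
  }
  list(fused = pmin(pmax(fused_raw, 0), 1), fused_raw = fused_raw,
       enhanced = enh, nir_term = fn, light = L, dark = dark, t = tmap,
       vi = vi, vi_comp = vic)
}
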