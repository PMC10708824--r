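test_that("vegetation index hits its closed-form anchors and range", {
  vis <- solid_rgb(c(0.3, 0.1, 0.1), 2, 2)
  pr <- registered_pair(vis, matrix(0.3, 2, 2))
  expect_equal(vegetation_index(pr)$vi, matrix(0, 2, 2))

  vis[, , 1] <- 0
  expect_equal(vegetation_index(registered_pair(vis, matrix(0.8, 2, 2)))$vi,
               matrix(1, 2, 2))
  vis[, , 1] <- 0.8
  expect_equal(vegetation_index(registered_pair(vis, matrix(0, 2, 2)))$vi,
               matrix(-1, 2, 2))

  vis[, , 1] <- 0.2
  vm <- vegetation_index(registered_pair(vis, matrix(0.6, 2, 2)))
  expect_equal(vm$vi, matrix(0.5, 2, 2))
  expect_equal(vm$vi_comp, matrix(0.5, 2, 2))

  # zero-reflectance guard
  vis[, , 1] <- 0
  vm0 <- vegetation_index(registered_pair(vis, matrix(0, 2, 2)))
  expect_equal(vm0$vi, matrix(0, 2, 2))
  expect_equal(vm0$vi_comp, matrix(1, 2, 2))
})

test_that("complement is the normalized inversion and an involution", {
  expect_equal(complement_image(0), 1)
  expect_equal(complement_image(1), 0)
  expect_equal(complement_image(100 / 255), 155 / 255)
  set.seed(2)
  img <- array(runif(48), dim = c(4, 4, 3))
  expect_equal(complement_image(complement_image(img)), img)
})

test_that("atmospheric light selects the lowest-VI pixels channelwise", {
  # lowest-VI pixel is white: L = (1,1,1)
  vis <- solid_rgb(c(0.2, 0.3, 0.4), 8, 8)
  vis[3, 5, ] <- 1
  nir <- matrix(0.9, 8, 8)
  nir[3, 5] <- 0            # red=1, nir=0: VI = -1, uniquely lowest
  pr <- registered_pair(vis, nir)
  L <- atmospheric_light(pr, vegetation_index(pr))
  expect_equal(L, c(1, 1, 1))

  # all-vegetation scene with one dark sky pixel (lowest VI)
  vis2 <- solid_rgb(c(0.05, 0.4, 0.3), 8, 8)
  nir2 <- matrix(0.95, 8, 8)
  vis2[6, 2, ] <- c(0.31, 0.21, 0.11)
  nir2[6, 2] <- 0.1          # VI < 0 only here
  pr2 <- registered_pair(vis2, nir2)
  expect_equal(atmospheric_light(pr2, vegetation_index(pr2)),
               c(0.31, 0.21, 0.11))
})

test_that("atmospheric light breaks uniform-VI ties in row-major order", {
  set.seed(4)
  h <- 5; w <- 6
  vis <- array(runif(h * w * 3), dim = c(h, w, 3))
  nir <- vis[, , 1]                    # VI identically 0
  pr <- registered_pair(vis, nir)
  k <- 3
  params <- fusion_params(light_percentile = k / (h * w))
  L <- atmospheric_light(pr, vegetation_index(pr), params)
  # first k row-major pixels are (1,1), (1,2), (1,3)
  expected <- sapply(1:3, function(c) max(vis[1, 1:k, c]))
  expect_equal(L, expected)
})

test_that("transmission map follows t = clamp((1 - omega) dark)", {
  img <- solid_rgb(c(0.5, 0.6, 0.7), 3, 3)   # dark = 0.5 with L = 1
  tm <- transmission_map(img, c(1, 1, 1), fusion_params(omega = 0.6))
  expect_equal(tm$dark, matrix(0.5, 3, 3))
  expect_equal(tm$t, matrix(0.2, 3, 3))

  # dark = 0 clamps to the floor
  tm0 <- transmission_map(solid_rgb(c(0, 0.5, 1), 2, 2), c(1, 1, 1),
                          fusion_params(omega = 0.6, t_floor = 0.1))
  expect_equal(tm0$t, matrix(0.1, 2, 2))

  # omega = 0: t equals the channel minimum
  tm2 <- transmission_map(solid_rgb(c(0.2, 0.5, 0.8), 2, 2), c(1, 1, 1),
                          fusion_params(omega = 0))
  expect_equal(tm2$t, matrix(0.2, 2, 2))

  # canonical form: t = 1 - omega * dark
  tmc <- transmission_map(img, c(1, 1, 1),
                          fusion_params(omega = 0.6,
                                        t_formula = "canonical"))
  expect_equal(tmc$t, matrix(1 - 0.6 * 0.5, 3, 3))
})

test_that("enhancement fixed points and scalar anchor", {
  L <- c(0.8, 0.8, 0.8)
  comp <- solid_rgb(c(0.8, 0.8, 0.8), 2, 2)
  tm <- list(t = matrix(0.5, 2, 2))
  # complement equal to L is a fixed point whatever t
  out <- enhance_image(comp, L, tm)
  expect_equal(out$raw, comp)

  comp2 <- solid_rgb(c(0.4, 0.4, 0.4), 2, 2)
  out2 <- enhance_image(comp2, L, tm)
  expect_equal(out2$raw[1, 1, 1], 0)     # 0.8 + (0.4 - 0.8)/0.5
  expect_equal(out2$enhanced[1, 1, 1], 1)

  # t = 1 is the identity: R' recovers the original polarity image
  set.seed(6)
  vis <- array(runif(27), dim = c(3, 3, 3))
  out3 <- enhance_image(1 - vis, c(0.5, 0.5, 0.5), list(t = matrix(1, 3, 3)))
  expect_equal(out3$enhanced, vis, tolerance = 1e-12)
})

test_that("NIR term preserves colour ratios and respects delta", {
  pr <- random_pair(6, 6, seed = 8)
  dark <- matrix(0.5, 6, 6)
  expect_equal(nir_term(pr, dark, fusion_params(delta = 0)),
               array(0, dim = c(6, 6, 3)))

  # gray pixel: each channel gets delta * N * D / 3
  vis <- solid_rgb(c(0.3, 0.3, 0.3), 2, 2)
  prg <- registered_pair(vis, matrix(0.6, 2, 2))
  fn <- nir_term(prg, matrix(0.5, 2, 2), fusion_params(delta = 0.5))
  expect_equal(fn[1, 1, ], rep(0.5 * 0.6 * 0.5 / 3, 3), tolerance = 1e-5)

  # black VIS pixel is epsilon-guarded to ~0
  prb <- registered_pair(solid_rgb(c(0, 0, 0), 2, 2), matrix(0.9, 2, 2))
  fnb <- nir_term(prb, matrix(2, 2, 2), fusion_params())
  expect_equal(max(abs(fnb)), 0)
})

test_that("fusion identities hold exactly", {
  # delta = 0 with VI' = 0 everywhere: output is the input
  pr <- all_vegetation_pair(8, 8, seed = 10)
  fr <- fuse_pair(pr, fusion_params(delta = 0))
  expect_equal(max(fr$weights), 0)
  expect_equal(fr$fused, pr$vis, tolerance = 1e-12)

  # w = 1 with delta = 0: output is exactly the enhanced image
  set.seed(12)
  vis <- array(runif(48, 0.2, 0.8), dim = c(4, 4, 3))
  prw <- registered_pair(vis, matrix(0, 4, 4))   # VI <= 0: VI' = 1
  frw <- fuse_pair(prw, fusion_params(delta = 0, omega = 0, t_floor = 1))
  expect_equal(frw$weights, matrix(1, 4, 4))
  expect_equal(frw$fused, frw$enhanced)
})

test_that("fused output is always within [0, 1]", {
  for (seed in 1:5) {
    pr <- random_pair(10, 9, seed = seed)
    fr <- fuse_pair(pr, fusion_params(delta = runif(1), omega = runif(1, 0, 0.9)))
    expect_gte(min(fr$fused), 0)
    expect_lte(max(fr$fused), 1)
    expect_gte(min(fr$weights), 0)
    expect_lte(max(fr$weights), 1)
  }
})

test_that("pre-NIR fusion is a convex blend of original and enhanced", {
  pr <- random_pair(9, 9, seed = 21)
  fr <- fuse_pair(pr, fusion_params(delta = 0))
  lo <- pmin(pr$vis, fr$enhanced)
  hi <- pmax(pr$vis, fr$enhanced)
  expect_true(all(fr$fused_raw >= lo - 1e-12))
  expect_true(all(fr$fused_raw <= hi + 1e-12))
})

test_that("enhancement amplification is non-decreasing in omega", {
  pr <- random_pair(8, 8, seed = 14)
  prev <- NULL
  for (om in seq(0, 0.8, by = 0.2)) {
    fr <- fuse_pair(pr, fusion_params(omega = om))
    # |R - L| = |I' - L| / t per channel
    amp <- array(0, dim = dim(pr$vis))
    for (c in 1:3) {
      amp[, , c] <- abs((1 - pr$vis[, , c]) - fr$light[c]) / fr$tmap$t
    }
    if (!is.null(prev)) expect_true(all(amp >= prev - 1e-9))
    prev <- amp
  }
})

test_that("fused output before clipping is non-decreasing in delta", {
  pr <- random_pair(8, 8, seed = 15)
  prev <- NULL
  for (dl in seq(0, 1, by = 0.25)) {
    fr <- fuse_pair(pr, fusion_params(delta = dl))
    if (!is.null(prev)) expect_true(all(fr$fused_raw >= prev - 1e-12))
    prev <- fr$fused_raw
  }
})

test_that("vectorized pipeline matches the per-pixel oracle", {
  set.seed(100)
  for (rep in 1:10) {
    h <- sample(8:16, 1); w <- sample(8:16, 1)
    pr <- random_pair(h, w, seed = 1000 + rep)
    params <- fusion_params(delta = runif(1), omega = runif(1, 0, 0.9),
                            dark_source = sample(c("original", "complement"), 1),
                            t_formula = sample(c("literal", "canonical"), 1))
    fr <- fuse_pair(pr, params)
    or <- oracle_fuse(pr, params)
    expect_equal(fr$light, or$light, tolerance = 1e-12)
    expect_lt(max(abs(fr$fused - or$fused)), 1e-9)
    expect_lt(max(abs(fr$enhanced - or$enhanced)), 1e-9)
    expect_lt(max(abs(fr$nir_term - or$nir_term)), 1e-9)
    expect_lt(max(abs(fr$tmap$t - or$t)), 1e-9)
  }
})

test_that("fusion results tidy, glance and write to disk", {
  sc <- generate_scene(scene_spec(seed = 2, exposure = 0.25, height = 64,
                                  width = 64, fruit_count = 2))
  fr <- fuse_pair(sc$pair)
  td <- tidy(fr)
  expect_equal(td$image, c("original", "enhanced", "fused"))
  gl <- glance(fr)
  expect_equal(gl$contrast_gain,
               td$contrast[td$image == "fused"] -
                 td$contrast[td$image == "original"])
  d <- withr::local_tempdir()
  write_fusion(fr, file.path(d, "f.png"), debug_maps = TRUE)
  expect_true(all(file.exists(file.path(d, c("f.png", "f_vi.png", "f_t.png",
                                             "f_w.png")))))
  p <- autoplot(fr)
  expect_s3_class(p, "ggplot")
})
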