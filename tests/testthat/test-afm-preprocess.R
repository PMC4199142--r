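test_that("flattening a constant image yields all zeros", {
  img <- height_image(matrix(3.7, 16, 16), 4)
  out <- flatten_scanlines(img, order = 0)
  expect_equal(out$values, matrix(0, 16, 16))
})

test_that("flattening is invariant to injected per-row offsets", {
  cfg <- quiet_config(pixel_scale = 4, image_size = 128, rng_seed = 2)
  r <- render_chain_image(control_preset(), 5, cfg)
  base <- r$image
  offs <- seq(-5, 5, length.out = nrow(base$values))
  shifted <- height_image(base$values + offs, base$pixel_scale)
  f0 <- flatten_scanlines(base, 0)
  f1 <- flatten_scanlines(shifted, 0)
  expect_equal(f0$values, f1$values, tolerance = 1e-12)
})

test_that("order-1 flattening removes per-row tilt", {
  nr <- 32; nc <- 64
  tilt <- outer(runif(nr, -0.2, 0.2), seq_len(nc))
  img <- height_image(tilt + rnorm(nr * nc, 0, 0.01), 4)
  out <- flatten_scanlines(img, order = 1)
  expect_lt(max(abs(apply(out$values, 1, median))), 1e-6)
  expect_lt(stats::sd(out$values), 0.05)
  expect_error(flatten_scanlines(img, order = 2), "order")
})

test_that("scanline offsets do not change detected bead positions", {
  cfg_off <- chain_render_config(pixel_scale = 4, image_size = 256,
                                 noise_sd = 0, scanline_offset_sd = 5,
                                 rng_seed = 31)
  cfg_clean <- chain_render_config(pixel_scale = 4, image_size = 256,
                                   noise_sd = 0, scanline_offset_sd = 0,
                                   rng_seed = 31)
  a <- render_chain_image(control_preset(), c(6, 8), cfg_off)
  b <- render_chain_image(control_preset(), c(6, 8), cfg_clean)
  expect_identical(a$beads, b$beads)  # same seed, same geometry
  da <- attr(afm_pipeline(a$image), "beads")
  db <- attr(afm_pipeline(b$image), "beads")
  expect_equal(nrow(da), nrow(db))
  expect_equal(da$x_nm, db$x_nm, tolerance = 1)
  expect_equal(da$y_nm, db$y_nm, tolerance = 1)
})

test_that("artifact masking flags large blobs and only large blobs", {
  cfg <- chain_render_config(pixel_scale = 4, image_size = 256,
                             noise_sd = 1, rng_seed = 13)
  clean <- render_chain_image(control_preset(), c(8, 8), cfg)
  m0 <- mask_artifacts(flatten_scanlines(clean$image))
  expect_false(any(m0))

  cfg$artifact_density <- 3L
  dirty <- render_chain_image(control_preset(), c(8, 8), cfg)
  m1 <- mask_artifacts(flatten_scanlines(dirty$image))
  expect_equal(nrow(dirty$artifacts), 3L)
  for (i in seq_len(3)) {
    r <- round(dirty$artifacts$y_nm[i] / 4 + 1)
    c <- round(dirty$artifacts$x_nm[i] / 4 + 1)
    expect_true(m1[r, c])
  }
})

test_that("a saturated frame is fully masked and yields no beads", {
  img <- height_image(matrix(65535, 32, 32), 4)
  m <- mask_artifacts(img)
  expect_true(all(m))
  det <- detect_beads(img, mask = m, smoothing_sigma = 6,
                      min_prominence = 1, min_separation = 30)
  expect_equal(nrow(det), 0L)
})

test_that("contrast inversion is an involution preserving positions", {
  cfg <- quiet_config(pixel_scale = 4, image_size = 128, rng_seed = 6)
  r <- render_chain_image(control_preset(), 5, cfg)
  inv <- invert_contrast(r$image)
  back <- invert_contrast(inv)
  expect_equal(back$values, r$image$values, tolerance = 1e-12)
  const <- height_image(matrix(2, 8, 8), 4)
  expect_equal(invert_contrast(const)$values, matrix(2, 8, 8))
  up <- detect_beads(r$image, smoothing_sigma = 6, min_prominence = 3,
                     min_separation = 30, polarity = "bright")
  dn <- detect_beads(inv, smoothing_sigma = 6, min_prominence = 3,
                     min_separation = 30, polarity = "dark")
  expect_equal(up$x_nm, dn$x_nm, tolerance = 1e-6)
  expect_equal(up$y_nm, dn$y_nm, tolerance = 1e-6)
})
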