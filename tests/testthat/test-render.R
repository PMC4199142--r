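test_that("a noise-free 3-bead chain renders exactly 3 maxima at truth", {
  cfg <- quiet_config(pixel_scale = 4, image_size = 128, rng_seed = 5)
  r <- render_chain_image(delta_preset(56), 3, cfg)
  expect_equal(nrow(r$beads), 3L)
  expect_equal(r$periodicities, rep(56, 2), tolerance = 1e-3)
  det <- detect_beads(r$image, smoothing_sigma = 6, min_prominence = 3,
                      min_separation = 30)
  expect_equal(nrow(det), 3L)
  expect_true(all(match_distances(det, r$beads) <= cfg$pixel_scale))
})

test_that("zero chains give a pure-noise image with empty ground truth", {
  cfg <- chain_render_config(image_size = 64, noise_sd = 1, rng_seed = 3)
  r <- render_chain_image(control_preset(), integer(0), cfg)
  expect_equal(nrow(r$beads), 0L)
  expect_length(r$periodicities, 0)
  expect_equal(dim(r$image$values), c(64L, 64L))
})

test_that("rendered bead count always equals the ground-truth row count", {
  for (s in 1:5) {
    lens <- sample_chain_lengths(8, 3, 3, seed = s)
    r <- render_chain_image(control_preset(), lens,
                            chain_render_config(image_size = 400,
                                                rng_seed = s))
    expect_identical(nrow(r$beads), sum(lens))
    expect_identical(r$chains$n_beads, lens)
    expect_length(r$periodicities, sum(lens) - length(lens))
  }
})

test_that("fixed seed gives bit-identical images and ground truth", {
  cfg <- chain_render_config(image_size = 256, artifact_density = 1,
                             rng_seed = 77)
  a <- render_chain_image(control_preset(), c(5, 7), cfg)
  b <- render_chain_image(control_preset(), c(5, 7), cfg)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$beads, b$beads)
})

test_that("detection recovers >= 95% of beads within 1 px at default noise", {
  cfg <- chain_render_config(pixel_scale = 4, image_size = 512,
                             noise_sd = 1, rng_seed = 21)  # 10% of amplitude
  r <- render_chain_image(control_preset(), c(12, 9, 7, 10, 8), cfg)
  res <- afm_pipeline(r$image)
  det <- attr(res, "beads")
  d <- match_distances(det, r$beads)
  expect_gte(mean(d <= cfg$pixel_scale), 0.95)
})

test_that("impossible placements fail with an informative error", {
  cfg <- quiet_config(pixel_scale = 4, image_size = 64, rng_seed = 1)
  expect_error(render_chain_image(control_preset(), 200, cfg),
               "placement failed")
})

test_that("render_chain_dataset spreads chains over images, ids unique", {
  lens <- sample_chain_lengths(10, 4, 7, seed = 4)
  ds <- render_chain_dataset(control_preset(), lens,
                             chain_render_config(image_size = 480,
                                                 rng_seed = 8),
                             chains_per_image = 3)
  ids <- unlist(lapply(ds, function(r) r$chains$chain_id))
  expect_identical(sort(ids), seq_along(lens))
  counts <- unlist(lapply(ds, function(r) r$chains$n_beads))
  expect_identical(sort(counts), sort(lens))
})
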