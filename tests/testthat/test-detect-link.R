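test_that("a single noise-free bump is located at its true position", {
  v <- matrix(0, 64, 64)
  img0 <- height_image(v, 2)
  # bump centred at 0-based pixel (row 32, col 48) -> (x, y) = (96, 64) nm
  for (r in 1:64) for (c in 1:64)
    v[r, c] <- 10 * exp(-((r - 33)^2 + (c - 49)^2) / (2 * 2^2))
  img <- height_image(v, 2)
  det <- detect_beads(img, smoothing_sigma = 4, min_prominence = 3,
                      min_separation = 10)
  expect_equal(nrow(det), 1L)
  expect_equal(det$x_nm, 96, tolerance = 2)
  expect_equal(det$y_nm, 64, tolerance = 2)
})

test_that("detection matches the brute-force local-maximum oracle", {
  for (s in 1:6) {
    cfg <- chain_render_config(pixel_scale = 4, image_size = 64,
                               noise_sd = 1, scanline_offset_sd = 0,
                               rng_seed = s)
    r <- render_chain_image(control_preset(), 3, cfg)
    det <- detect_beads(r$image, smoothing_sigma = 6, min_prominence = 3,
                        min_separation = 30)
    sm <- brute_smooth(r$image$values, 6 / 4)
    oracle <- brute_force_maxima(sm, 3, 30 / 4)
    expect_equal(nrow(det), nrow(oracle))
    if (nrow(det) > 0) {
      ord_d <- order(det$row, det$col)
      ord_o <- order(oracle[, 1], oracle[, 2])
      d_px <- sqrt((det$y_nm[ord_d] / 4 + 1 - oracle[ord_o, 1])^2 +
                   (det$x_nm[ord_d] / 4 + 1 - oracle[ord_o, 2])^2)
      expect_true(all(d_px <= 0.5))
    }
  }
})

test_that("pure-noise images produce almost no spurious beads", {
  spurious <- vapply(1:20, function(s) {
    cfg <- chain_render_config(pixel_scale = 4, image_size = 128,
                               noise_sd = 1, rng_seed = 100 + s)
    r <- render_chain_image(control_preset(), integer(0), cfg)
    nrow(attr(afm_pipeline(r$image), "beads"))
  }, numeric(1))
  expect_lte(mean(spurious), 1)
})

test_that("whole-pixel translation shifts all centroids exactly", {
  cfg <- quiet_config(pixel_scale = 4, image_size = 128, rng_seed = 17)
  r <- render_chain_image(control_preset(), 4, cfg)
  v <- r$image$values
  sh <- matrix(0, 128, 128)
  sh[11:128, 6:128] <- v[1:118, 1:123]  # shift by (+10 rows, +5 cols)
  a <- detect_beads(r$image, smoothing_sigma = 6, min_prominence = 3,
                    min_separation = 30)
  b <- detect_beads(height_image(sh, 4), smoothing_sigma = 6,
                    min_prominence = 3, min_separation = 30)
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$row, a$col), ]; b <- b[order(b$row, b$col), ]
  expect_equal(b$x_nm - a$x_nm, rep(5 * 4, nrow(a)), tolerance = 0.05)
  expect_equal(b$y_nm - a$y_nm, rep(10 * 4, nrow(a)), tolerance = 0.05)
})

test_that("smoothing sigma below the pixel scale warns and clamps", {
  img <- height_image(matrix(rnorm(256), 16, 16), 4)
  expect_warning(detect_beads(img, smoothing_sigma = 1, min_prominence = 10,
                              min_separation = 30), "clamped")
  expect_error(detect_beads(img, smoothing_sigma = 6, min_prominence = 1,
                            min_separation = 4), "min_separation")
})

test_that("two well-separated lines of beads link into two chains", {
  y1 <- rep(0, 5); y2 <- rep(5 * 125, 5)  # 5 * max_link apart
  beads <- data.frame(x_nm = c((0:4) * 56, (0:4) * 56),
                      y_nm = c(y1, y2))
  chains <- link_chains(beads, max_link = 125, max_turn = 60)
  expect_length(chains, 2L)
  expect_identical(sort(vapply(chains, `[[`, integer(1), "bead_count")),
                   c(5L, 5L))
  for (ch in chains)
    expect_equal(ch$repeats, rep(56, 4), tolerance = 1e-9)
})

test_that("equidistant ties are broken by bead index, deterministically", {
  # bead 1 equidistant from beads 2 and 3; the smaller index wins first
  beads <- data.frame(x_nm = c(0, 56, -56), y_nm = c(0, 0, 0))
  a <- link_chains(beads, max_link = 60, max_turn = 60)
  b <- link_chains(beads, max_link = 60, max_turn = 60)
  expect_identical(a, b)
  expect_length(a, 1L)
  expect_equal(a[[1]]$bead_count, 3L)
})

test_that("sharp turns beyond max_turn are not linked", {
  beads <- data.frame(x_nm = c(0, 56, 56), y_nm = c(0, 0, 56))
  open_chain <- link_chains(beads, max_link = 60, max_turn = 95)
  expect_equal(open_chain[[1]]$bead_count, 3L)
  bent <- link_chains(beads, max_link = 60, max_turn = 60)
  expect_equal(max(vapply(bent, `[[`, integer(1), "bead_count")), 2L)
})

test_that("chain memberships recover the generator's ground truth", {
  cfg <- chain_render_config(pixel_scale = 4, image_size = 512,
                             noise_sd = 1, rng_seed = 23)
  r <- render_chain_image(control_preset(), c(9, 11, 6, 8, 7), cfg)
  res <- afm_pipeline(r$image)
  expect_equal(nrow(res$chains), 5L)
  expect_identical(sort(res$chains$bead_count), sort(r$chains$n_beads))
  # each measured chain's beads map onto exactly one true chain
  det <- attr(res, "beads")
  truth_chain <- r$beads$chain_id[
    vapply(seq_len(nrow(det)), function(i)
      which.min((r$beads$x_nm - det$x_nm[i])^2 +
                (r$beads$y_nm - det$y_nm[i])^2), integer(1))]
  relink <- link_chains(det)
  for (ch in relink) {
    idx <- vapply(seq_len(nrow(ch$beads)), function(i)
      which(det$x_nm == ch$beads$x_nm[i] &
            det$y_nm == ch$beads$y_nm[i])[1], integer(1))
    expect_length(unique(truth_chain[idx]), 1L)
  }
})
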