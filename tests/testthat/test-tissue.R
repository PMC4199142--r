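test_that("area fraction hits the trivial extremes", {
  sec <- render_tissue_section(layer_spec(size = 128), stain_fraction = 100,
                               seed = 1)
  expect_equal(area_fraction(sec$image)$percent, 100, tolerance = 0.5)
  sec0 <- render_tissue_section(layer_spec(size = 128), stain_fraction = 0,
                                seed = 1)
  # a stain-free channel has no bimodal histogram for Otsu: use the
  # calibrated fixed threshold for the absent-signal case
  expect_lt(area_fraction(sec0$image,
                          policy = list("fixed:0.5", "otsu"))$percent, 0.5)
})

test_that("area fraction recovers a 31% synthetic coverage", {
  sec <- render_tissue_section(layer_spec(size = 512), stain_fraction = 31,
                               seed = 2)
  expect_equal(sec$truth$stain_fraction, 31, tolerance = 0.5)
  af <- area_fraction(sec$image)
  expect_equal(af$percent, 31, tolerance = 1)
  # fixed thresholds work too
  af2 <- area_fraction(sec$image, policy = list("fixed:0.5", 0.5))
  expect_equal(af2$percent, 31, tolerance = 1)
})

test_that("area fraction is invariant under 90-degree rotations", {
  sec <- render_tissue_section(layer_spec(size = 256), stain_fraction = 31,
                               seed = 3)
  base <- area_fraction(sec$image)$percent
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  img_r <- tissue_image(lapply(sec$image$channels, rot),
                        sec$image$pixel_scale)
  expect_equal(area_fraction(img_r)$percent, base, tolerance = 1e-9)
})

test_that("voids are excluded from the tissue denominator", {
  sec <- render_tissue_section(layer_spec(size = 256), stain_fraction = 40,
                               void_fraction = 0.05, seed = 4)
  af <- area_fraction(sec$image)
  expect_equal(af$percent, 40, tolerance = 1.5)
  expect_equal(af$n_tissue, sum(sec$truth$tissue), tolerance = 0.02 *
                 sum(sec$truth$tissue))
})

test_that("a straight centerline reproduces the input band", {
  nr <- 64; nc <- 64
  ch <- matrix(rep(sin(seq_len(nr) / 5), nc), nr, nc)
  img <- tissue_image(list(tissue = ch), 1)
  cl <- data.frame(x_um = c(5, 20, 40, 60), y_um = rep(31.5, 4))
  st <- straighten_wall(img, cl, half_width = 20)
  # central rows of the straightened band equal the source rows
  mid <- (nrow(st$channels$tissue) + 1) / 2
  src_row <- 32  # y = 31.5 um -> pixel row 32
  expect_equal(st$channels$tissue[mid, 5:50],
               rep(ch[src_row, 1], 46), tolerance = 1e-6)
  off10 <- st$channels$tissue[mid + 10, 5:50]
  expect_equal(off10, rep(ch[src_row + 10, 1], 46), tolerance = 1e-6)
})

test_that("a full circle unrolls to its circumference", {
  R <- 60
  ang <- seq(0, 2 * pi, length.out = 41)
  cl <- data.frame(x_um = 100 + R * cos(ang), y_um = 100 + R * sin(ang))
  ch <- matrix(1, 200, 200)
  img <- tissue_image(list(tissue = ch), 1)
  st <- straighten_wall(img, cl, half_width = 15)
  expect_equal(attr(st, "arc_length_um"), 2 * pi * R,
               tolerance = 0.01 * 2 * pi * R)
})

test_that("tight curvature triggers the self-intersection guard", {
  R <- 10
  ang <- seq(0, 2 * pi, length.out = 33)
  cl <- data.frame(x_um = 50 + R * cos(ang), y_um = 50 + R * sin(ang))
  img <- tissue_image(list(tissue = matrix(1, 100, 100)), 1)
  expect_error(straighten_wall(img, cl, half_width = 30),
               "self-intersect")
})

test_that("an annular wall straightens to its true uniform thickness", {
  sec <- render_tissue_section(layer_spec("annulus", size = 512),
                               stain_fraction = 31, seed = 5)
  st <- straighten_wall(sec$image, sec$truth$centerline, half_width = 70)
  th <- medial_thickness(st)
  expect_equal(th$mean, sec$truth$thickness_um, tolerance = 1)
  expect_lt(th$sd, 1)
  # straightening preserves total medial area within 2%
  area_st <- sum(th$profile_um) * st$pixel_scale
  area_true <- sum(sec$truth$tissue) * sec$image$pixel_scale^2
  expect_equal(area_st, area_true, tolerance = 0.02 * area_true)
})

test_that("thickness counts only tissue pixels", {
  band <- matrix(0, 120, 50)
  band[16:105, ] <- 1  # 90 px thick wall
  img <- tissue_image(list(tissue = band), 1)
  th <- medial_thickness(img, policy = 0.5)
  expect_equal(th$mean, 90)
  expect_equal(unname(th$range), c(90, 90))
  holed <- band; holed[40:49, 10] <- 0  # a 10 px void in one column
  th2 <- medial_thickness(tissue_image(list(tissue = holed), 1),
                          policy = 0.5)
  expect_equal(sort(unique(th2$profile_um)), c(80, 90))
  empty_cols <- band; empty_cols[, 50] <- 0
  expect_message(
    th3 <- medial_thickness(tissue_image(list(tissue = empty_cols), 1),
                            policy = 0.5), "excluded")
  expect_equal(th3$n_columns, 49L)
})

test_that("regional gelatinase recovers prescribed intensities", {
  sec <- render_tissue_section(
    layer_spec(size = 512),
    regional_means = c(lamellar = 40.6, inter_lamellar = 51.6),
    background_level = 5, seed = 6)
  off <- !sec$truth$tissue &
    row(sec$truth$tissue) < which.max(rowSums(sec$truth$tissue)) - 10
  rg <- regional_gelatinase(
    sec$image,
    list(lamellar = sec$truth$lamellar,
         inter_lamellar = sec$truth$inter_lamellar),
    background = off)
  expect_equal(rg$mean_intensity_per_um2[rg$region == "lamellar"], 40.6,
               tolerance = 0.02 * 40.6)
  expect_equal(rg$mean_intensity_per_um2[rg$region == "inter_lamellar"],
               51.6, tolerance = 0.02 * 51.6)
})

test_that("gelatinase obeys trivial background identities", {
  ch <- matrix(10, 64, 64)
  img <- tissue_image(list(fitc = ch), 1)
  all_px <- matrix(TRUE, 64, 64)
  rg <- regional_gelatinase(img, list(all = all_px), background = 2)
  expect_equal(rg$mean_intensity_per_um2, 8)
  rg0 <- regional_gelatinase(img, list(all = all_px), background = 10)
  expect_equal(rg0$mean_intensity_per_um2, 0)
  expect_error(regional_gelatinase(img, list(bad = matrix(TRUE, 2, 2)),
                                   background = 0), "shape")
})

test_that("a region's intensity is the area-weighted mean of subregions", {
  sec <- render_tissue_section(layer_spec(size = 256), seed = 7)
  whole <- sec$truth$inter_lamellar
  top <- whole & (row(whole) <= 128)
  bot <- whole & (row(whole) > 128)
  rg <- regional_gelatinase(sec$image,
                            list(whole = whole, top = top, bot = bot),
                            background = 0)
  w <- rg$n_px[rg$region %in% c("top", "bot")]
  v <- rg$mean_intensity_per_um2[rg$region %in% c("top", "bot")]
  expect_equal(rg$mean_intensity_per_um2[rg$region == "whole"],
               sum(w * v) / sum(w), tolerance = 1e-9)
})

test_that("zymography strips tile the wall and are quantifiable", {
  sec <- render_tissue_section(layer_spec(size = 512), seed = 8)
  strips <- region_strips(sec$truth$tissue, strip_width_px = 100,
                          n_strips = 3)
  expect_length(strips, 3L)
  expect_true(all(vapply(strips, any, logical(1))))
  rg <- regional_gelatinase(sec$image, strips, background = 5)
  expect_equal(nrow(rg), 3L)
  expect_true(all(rg$mean_intensity_per_um2 > 0))
})
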