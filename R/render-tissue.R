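#' Layer geometry for synthetic tissue sections
#'
#' Describes an aortic-media-like wall of alternating elastic lamellae and
#' inter-lamellar bands, rendered either as straight horizontal bands or as
#' an annulus. The default geometry (7 lamellae of 3.1 um separated by
#' 11.5 um) gives a medial thickness of 90.7 um, a typical healthy rodent
#' aorta.
#'
#' @param mode `"straight"` or `"annulus"`.
#' @param size image size in pixels (side, or c(rows, cols)).
#' @param pixel_scale micrometres per pixel.
#' @param n_lamellae number of elastic lamellae.
#' @param lamellar_um thickness of each lamella (um).
#' @param inter_um thickness of each inter-lamellar band (um).
#' @param wall_offset_um for `"straight"`: depth of the intimal surface
#'   below the image top (um); for `"annulus"`: the lumen (inner) radius.
#' @return object of class `layer_spec`; `$thickness_um` is the total
#'   medial thickness.
#' @export
layer_spec <- function(mode = c("straight", "annulus"), size = 512,
                       pixel_scale = 1, n_lamellae = 7, lamellar_um = 3.1,
                       inter_um = 11.5, wall_offset_um = NULL) {
  mode <- match.arg(mode)
  size <- rep_len(as.integer(size), 2L)
  if (any(size < 16)) stop("image too small", call. = FALSE)
  if (lamellar_um <= 0 || inter_um <= 0 || n_lamellae < 1)
    stop("layer thicknesses must be positive", call. = FALSE)
  thick <- n_lamellae * lamellar_um + (n_lamellae - 1) * inter_um
  if (is.null(wall_offset_um))
    wall_offset_um <- if (mode == "straight")
      (size[1] * pixel_scale - thick) / 2
    else max(10, (min(size) * pixel_scale / 2 - thick) * 0.55)
  structure(list(mode = mode, size = size, pixel_scale = pixel_scale,
                 n_lamellae = n_lamellae, lamellar_um = lamellar_um,
                 inter_um = inter_um, wall_offset_um = wall_offset_um,
                 thickness_um = thick),
            class = "layer_spec")
}

# depth of each pixel centre into the wall (um): NA outside the wall.
# Also returns the lamellar / inter-lamellar classification.
wall_geometry <- function(spec) {
  nr <- spec$size[1]; nc <- spec$size[2]; sc <- spec$pixel_scale
  if (spec$mode == "straight") {
    y <- (seq_len(nr) - 0.5) * sc
    depth_row <- y - spec$wall_offset_um
    depth <- matrix(depth_row, nr, nc)
  } else {
    cx <- nc / 2 * sc; cy <- nr / 2 * sc
    xs <- (seq_len(nc) - 0.5) * sc
    ys <- (seq_len(nr) - 0.5) * sc
    rad <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
    depth <- rad - spec$wall_offset_um
  }
  inside <- depth >= 0 & depth < spec$thickness_um
  period <- spec$lamellar_um + spec$inter_um
  phase <- depth %% period
  lam <- inside & phase < spec$lamellar_um
  inter <- inside & !lam
  list(depth = depth, inside = inside, lamellar = lam, inter_lamellar = inter)
}

#' Render a synthetic tissue section with known ground truth
#'
#' Builds a multi-channel raster of a layered vessel wall: a `tissue`
#' channel (thresholdable tissue-vs-glass contrast, with optional voids), a
#' binary-plus-noise `stain` channel whose positive pixels cover exactly
#' the requested fraction of the tissue area (spatially clumped), a `fitc`
#' channel with prescribed mean intensities in the lamellar and
#' inter-lamellar regions over a uniform background, and a `wavespeed`
#' channel (m/s) with prescribed per-region means. All ground truth is
#' returned alongside the image.
#'
#' @param layers a [layer_spec()].
#' @param stain_fraction target stain coverage, percent of tissue area.
#' @param regional_means named numeric, mean FITC intensity (A.U.) for
#'   `lamellar` and `inter_lamellar` regions (above background).
#' @param wave_speed named list: for `lamellar` and `inter_lamellar`, a
#'   numeric c(mean, sd) in m/s.
#' @param background_level FITC background (added everywhere).
#' @param noise_sd relative channel noise (fraction of signal).
#' @param void_fraction fraction of tissue pixels turned into voids.
#' @param seed optional integer seed.
#' @return list with `image` (a [tissue_image()]) and `truth` (list:
#'   `stain_fraction`, `thickness_um`, `regional_means`, `wave_speed`,
#'   `background_level`, plus logical masks `tissue`, `lamellar`,
#'   `inter_lamellar` and, for annuli, `centerline` control points).
#' @export
render_tissue_section <- function(layers = layer_spec(),
                                  stain_fraction = 31,
                                  regional_means = c(lamellar = 20,
                                                     inter_lamellar = 45),
                                  wave_speed = list(
                                    lamellar = c(1883, 6),
                                    inter_lamellar = c(1850, 8)),
                                  background_level = 5,
                                  noise_sd = 0.02,
                                  void_fraction = 0,
                                  seed = NULL) {
  stopifnot(inherits(layers, "layer_spec"))
  if (stain_fraction < 0 || stain_fraction > 100)
    stop("stain_fraction must be in [0, 100]", call. = FALSE)
  with_seed(seed, {
    geo <- wall_geometry(layers)
    nr <- layers$size[1]; nc <- layers$size[2]
    tissue_mask <- geo$inside
    if (void_fraction > 0) {
      idx <- which(tissue_mask)
      holes <- sample(idx, round(void_fraction * length(idx)))
      tissue_mask[holes] <- FALSE
    }
    n_tissue <- sum(tissue_mask)
    if (n_tissue == 0) stop("no tissue pixels in field", call. = FALSE)

    n_stain <- round(stain_fraction / 100 * n_tissue)
    realized <- 100 * n_stain / n_tissue
    if (abs(realized - stain_fraction) > 0.5)
      stop(sprintf(
        "stain fraction %.3f%% unreachable at this resolution (closest %.3f%%)",
        stain_fraction, realized), call. = FALSE)
    # clumped coverage: take the top-n pixels of a smoothed noise field
    field <- ebimage_gblur(matrix(rnorm(nr * nc), nr, nc), 3)
    stain_mask <- matrix(FALSE, nr, nc)
    if (n_stain > 0) {
      tidx <- which(tissue_mask)
      ord <- tidx[order(-field[tidx])]
      stain_mask[ord[seq_len(n_stain)]] <- TRUE
    }

    rel_noise <- function(base) base * (1 + rnorm(length(base), 0, noise_sd))
    tissue_ch <- matrix(0.05, nr, nc)
    tissue_ch[tissue_mask] <- 1
    tissue_ch <- matrix(rel_noise(tissue_ch), nr, nc)
    stain_ch <- matrix(0.05, nr, nc)
    stain_ch[stain_mask] <- 1
    stain_ch <- matrix(rel_noise(stain_ch), nr, nc)

    fitc <- matrix(background_level, nr, nc)
    fitc[geo$lamellar] <- background_level + regional_means[["lamellar"]]
    fitc[geo$inter_lamellar] <- background_level +
      regional_means[["inter_lamellar"]]
    fitc <- fitc + matrix(rnorm(nr * nc, 0,
                                noise_sd * max(regional_means)), nr, nc)

    ws <- matrix(1500, nr, nc)  # coupling-fluid-like background
    ws[geo$lamellar] <- rnorm(sum(geo$lamellar),
                              wave_speed$lamellar[1], wave_speed$lamellar[2])
    ws[geo$inter_lamellar] <- rnorm(sum(geo$inter_lamellar),
                                    wave_speed$inter_lamellar[1],
                                    wave_speed$inter_lamellar[2])

    truth <- list(stain_fraction = realized,
                  thickness_um = layers$thickness_um,
                  regional_means = regional_means,
                  wave_speed = wave_speed,
                  background_level = background_level,
                  tissue = tissue_mask,
                  lamellar = geo$lamellar,
                  inter_lamellar = geo$inter_lamellar)
    if (layers$mode == "annulus") {
      sc <- layers$pixel_scale
      r_mid <- layers$wall_offset_um + layers$thickness_um / 2
      ang <- seq(0, 2 * pi, length.out = 33)
      truth$centerline <- data.frame(
        x_um = nc / 2 * sc + r_mid * cos(ang),
        y_um = nr / 2 * sc + r_mid * sin(ang))
      truth$r_mid_um <- r_mid
    }
    list(image = tissue_image(
           list(tissue = tissue_ch, stain = stain_ch, fitc = fitc,
                wavespeed = ws),
           layers$pixel_scale,
           void_mask = if (void_fraction > 0) geo$inside & !tissue_mask
                       else NULL),
         truth = truth)
  })
}
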