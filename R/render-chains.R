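#' Rendering configuration for synthetic AFM chain images
#'
#' Controls the imaging conditions emulated by [render_chain_image()]:
#' physical sampling, bead appearance, scanline noise, white pixel noise and
#' large blob artifacts (surface impurities).
#'
#' @param pixel_scale nm per pixel.
#' @param image_size image side length in pixels (square image) or a
#'   length-2 vector (rows, cols).
#' @param bead_amplitude bead peak height (height units).
#' @param bead_radius bead radius (nm); beads are rendered as radially
#'   symmetric Gaussian bumps with sigma = bead_radius / 2.
#' @param noise_sd white pixel noise SD (height units).
#' @param scanline_offset_sd SD of per-row height offsets (height units),
#'   emulating scan line noise.
#' @param artifact_density number of large blob artifacts per image.
#' @param turn_sd SD of the per-step direction change of a chain path
#'   (degrees); changes are capped at `max_step_turn`.
#' @param max_step_turn hard cap on the per-step direction change (degrees).
#' @param rng_seed optional integer seed used by the renderer.
#' @return object of class `chain_render_config`.
#' @export
chain_render_config <- function(pixel_scale = 4, image_size = 512,
                                bead_amplitude = 10, bead_radius = 12,
                                noise_sd = 1, scanline_offset_sd = 0.5,
                                artifact_density = 0, turn_sd = 12,
                                max_step_turn = 25, rng_seed = NULL) {
  if (pixel_scale <= 0) stop("pixel_scale must be > 0", call. = FALSE)
  image_size <- rep_len(as.integer(image_size), 2L)
  if (any(image_size < 8L)) stop("image dimensions too small", call. = FALSE)
  if (bead_radius <= 0 || bead_amplitude <= 0)
    stop("bead_radius and bead_amplitude must be > 0", call. = FALSE)
  if (noise_sd < 0 || scanline_offset_sd < 0 || artifact_density < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(pixel_scale = pixel_scale, image_size = image_size,
                 bead_amplitude = bead_amplitude, bead_radius = bead_radius,
                 noise_sd = noise_sd, scanline_offset_sd = scanline_offset_sd,
                 artifact_density = as.integer(artifact_density),
                 turn_sd = turn_sd, max_step_turn = max_step_turn,
                 rng_seed = rng_seed),
            class = "chain_render_config")
}

# Draw a Gaussian bump of amplitude A and sigma (px) centred at floating
# pixel (row, col) into `values`, in place via return.
add_bump <- function(values, row, col, A, sigma_px) {
  r0 <- max(1L, floor(row - 4 * sigma_px))
  r1 <- min(nrow(values), ceiling(row + 4 * sigma_px))
  c0 <- max(1L, floor(col - 4 * sigma_px))
  c1 <- min(ncol(values), ceiling(col + 4 * sigma_px))
  if (r0 > r1 || c0 > c1) return(values)
  rr <- r0:r1; cc <- c0:c1
  bump <- A * outer(exp(-(rr - row)^2 / (2 * sigma_px^2)),
                    exp(-(cc - col)^2 / (2 * sigma_px^2)))
  values[rr, cc] <- values[rr, cc] + bump
  values
}

# Grow one chain path of `n_beads` beads with spacings drawn from `preset`,
# inside a field of `field` nm (c(width, height)), keeping `clear_other` nm
# from `other` beads (2-col matrix, may have 0 rows) and `clear_self` nm
# from its own beads more than 2 indices back. Returns a 2-col matrix of
# (x, y) nm or NULL on failure.
grow_chain <- function(n_beads, preset, field, margin, other,
                       clear_other, clear_self, turn_sd, max_turn_rad) {
  pos <- matrix(NA_real_, n_beads, 2)
  pos[1, ] <- runif(2, margin, field - margin)
  theta <- runif(1, 0, 2 * pi)
  centre <- field / 2
  for (j in 2:n_beads) {
    d <- unclass(sample_periodicities(preset, 1))
    ok <- FALSE
    for (try in 1:25) {
      dth <- rnorm(1, 0, turn_sd)
      dth <- max(-max_turn_rad, min(max_turn_rad, dth))
      th <- theta + dth
      cand <- pos[j - 1, ] + d * c(cos(th), sin(th))
      # steer towards the field centre when drifting outside the margin
      if (any(cand < margin) || any(cand > field - margin)) {
        aim <- atan2(centre[2] - pos[j - 1, 2], centre[1] - pos[j - 1, 1])
        dth <- atan2(sin(aim - theta), cos(aim - theta))
        dth <- max(-max_turn_rad, min(max_turn_rad, dth))
        th <- theta + dth
        cand <- pos[j - 1, ] + d * c(cos(th), sin(th))
        if (any(cand < margin) || any(cand > field - margin)) next
      }
      if (nrow(other) > 0) {
        d2 <- (other[, 1] - cand[1])^2 + (other[, 2] - cand[2])^2
        if (any(d2 < clear_other^2)) next
      }
      if (j > 3) {
        prev <- pos[1:(j - 3), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2
        if (any(d2 < clear_self^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
    pos[j, ] <- cand
    theta <- th
  }
  pos
}

#' Render a synthetic AFM height image of beaded microfibril chains
#'
#' Lays one chain per requested length along a smooth low-curvature random
#' path, with consecutive bead spacings drawn from the periodicity preset,
#' then renders beads as radially symmetric Gaussian bumps and adds per-row
#' scanline offsets, white pixel noise and (optionally) large blob
#' artifacts. Distinct chains, and non-neighbouring beads of one chain, are
#' kept well separated so that the ground-truth chain partition is
#' unambiguous.
#'
#' @param preset a [lorentz_preset()] for the bead spacings.
#' @param lengths integer vector of bead counts, one chain per entry; may be
#'   empty (pure-noise image).
#' @param config a [chain_render_config()].
#' @return list with elements
#'   \describe{
#'     \item{image}{the rendered [height_image()]}
#'     \item{beads}{ground-truth bead table: `chain_id`, `bead_idx`,
#'       `x_nm`, `y_nm`}
#'     \item{chains}{per-chain table: `chain_id`, `n_beads`}
#'     \item{periodicities}{numeric vector of true consecutive spacings}
#'     \item{artifacts}{table of blob artifact centres and radii (nm)}
#'   }
#' @export
render_chain_image <- function(preset, lengths, config = chain_render_config()) {
  stopifnot(inherits(preset, "lorentz_preset"),
            inherits(config, "chain_render_config"))
  lengths <- as.integer(lengths)
  if (any(lengths < 2L)) stop("each chain needs >= 2 beads", call. = FALSE)
  if (config$bead_radius >= preset$trunc[1] / 2)
    stop("bead_radius must be below half the minimum bead spacing",
         call. = FALSE)
  with_seed(config$rng_seed, {
    nr <- config$image_size[1]; nc <- config$image_size[2]
    field <- c(nc, nr) * config$pixel_scale  # (x extent, y extent) nm
    margin <- 3 * config$bead_radius
    clear_other <- 140; clear_self <- 100
    turn_sd <- config$turn_sd * pi / 180
    max_turn <- config$max_step_turn * pi / 180

    placed <- matrix(numeric(0), 0, 2)
    bead_rows <- list()
    for (ci in seq_along(lengths)) {
      pos <- NULL
      for (attempt in 1:60) {
        pos <- grow_chain(lengths[ci], preset, field, margin, placed,
                          clear_other, clear_self, turn_sd, max_turn)
        if (!is.null(pos)) break
      }
      if (is.null(pos))
        stop("chain placement failed: chain ", ci, " (", lengths[ci],
             " beads) does not fit the ", nr, "x", nc,
             " px field after bounded retries", call. = FALSE)
      placed <- rbind(placed, pos)
      bead_rows[[ci]] <- data.frame(chain_id = ci,
                                    bead_idx = seq_len(lengths[ci]),
                                    x_nm = pos[, 1], y_nm = pos[, 2])
    }
    beads <- if (length(bead_rows)) do.call(rbind, bead_rows)
             else data.frame(chain_id = integer(0), bead_idx = integer(0),
                             x_nm = numeric(0), y_nm = numeric(0))

    values <- matrix(0, nr, nc)
    sigma_px <- config$bead_radius / 2 / config$pixel_scale
    if (nrow(beads) > 0)
      for (i in seq_len(nrow(beads)))
        values <- add_bump(values,
                           nm_to_px(beads$y_nm[i], config$pixel_scale),
                           nm_to_px(beads$x_nm[i], config$pixel_scale),
                           config$bead_amplitude, sigma_px)

    artifacts <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                            radius_nm = numeric(0))
    if (config$artifact_density > 0) {
      for (a in seq_len(config$artifact_density)) {
        for (try in 1:100) {
          cand <- runif(2, margin, field - margin)
          rad <- runif(1, 30, 60)
          if (nrow(beads) == 0 ||
              all((beads$x_nm - cand[1])^2 + (beads$y_nm - cand[2])^2 >
                  (rad + 80)^2)) {
            amp <- config$bead_amplitude * runif(1, 2.5, 4)
            values <- add_bump(values,
                               nm_to_px(cand[2], config$pixel_scale),
                               nm_to_px(cand[1], config$pixel_scale),
                               amp, rad / config$pixel_scale)
            artifacts <- rbind(artifacts,
                               data.frame(x_nm = cand[1], y_nm = cand[2],
                                          radius_nm = rad))
            break
          }
        }
      }
    }

    if (config$scanline_offset_sd > 0)
      values <- values + rnorm(nr, 0, config$scanline_offset_sd)
    if (config$noise_sd > 0)
      values <- values + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)

    per <- numeric(0)
    if (nrow(beads) > 0)
      per <- unlist(lapply(split(beads, beads$chain_id), function(b)
        sqrt(diff(b$x_nm)^2 + diff(b$y_nm)^2)), use.names = FALSE)

    list(image = height_image(values, config$pixel_scale),
         beads = beads,
         chains = data.frame(chain_id = seq_along(lengths),
                             n_beads = lengths),
         periodicities = per,
         artifacts = artifacts)
  })
}

#' Render a set of chains across as many images as needed
#'
#' Distributes chains over images with at most `chains_per_image` chains
#' each; a chain that cannot be placed in the current image opens a fresh
#' one. Chain ids are unique across the whole set.
#'
#' @inheritParams render_chain_image
#' @param chains_per_image maximum chains per image.
#' @return list of [render_chain_image()] results; chain ids in each
#'   element's tables are globally unique.
#' @export
render_chain_dataset <- function(preset, lengths,
                                 config = chain_render_config(),
                                 chains_per_image = 4) {
  lengths <- as.integer(lengths)
  # render long chains first so they get empty fields
  ord <- order(lengths, decreasing = TRUE)
  lengths <- lengths[ord]
  out <- list(); i <- 1L; next_id <- 0L
  seed_i <- config$rng_seed
  while (i <= length(lengths)) {
    batch <- lengths[i:min(length(lengths), i + chains_per_image - 1L)]
    cfg <- config
    cfg$rng_seed <- seed_i
    res <- tryCatch(render_chain_image(preset, batch, cfg),
                    error = function(e) NULL)
    while (is.null(res) && length(batch) > 1L) {
      batch <- batch[-length(batch)]
      res <- tryCatch(render_chain_image(preset, batch, cfg),
                      error = function(e) NULL)
    }
    if (is.null(res))
      stop("chain of ", batch[1], " beads cannot be placed even alone; ",
           "increase image_size", call. = FALSE)
    res$beads$chain_id <- res$beads$chain_id + next_id
    res$chains$chain_id <- res$chains$chain_id + next_id
    next_id <- next_id + nrow(res$chains)
    out[[length(out) + 1L]] <- res
    i <- i + length(batch)
    if (!is.null(seed_i)) seed_i <- seed_i + 1L
  }
  out
}
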