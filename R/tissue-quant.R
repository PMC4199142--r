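# Resolve a threshold policy ("otsu", "fixed:<t>", or a number) for one
# channel. Otsu is computed on the channel rescaled to [0, 1].
resolve_threshold <- function(ch, policy) {
  if (is.numeric(policy)) return(policy)
  if (identical(policy, "otsu")) {
    lo <- min(ch); hi <- max(ch)
    if (hi <= lo) return(hi)
    t01 <- EBImage::otsu(EBImage::Image((ch - lo) / (hi - lo)))
    return(lo + t01 * (hi - lo))
  }
  if (grepl("^fixed:", policy))
    return(as.numeric(sub("^fixed:", "", policy)))
  stop("unknown threshold policy: ", policy, call. = FALSE)
}

#' Stain-positive area as a percentage of tissue area
#'
#' Thresholds the tissue channel to obtain the tissue mask (excluding voids
#' and glass) and the signal channel to obtain the stain-positive mask, and
#' reports the stain-positive tissue area as a percentage of total tissue
#' area.
#'
#' @param img a [tissue_image()].
#' @param signal_channel,tissue_channel channel names.
#' @param policy threshold policy applied to both channels: `"otsu"`,
#'   `"fixed:<t>"`, or a numeric threshold; a length-2 list/vector gives
#'   separate policies for (signal, tissue).
#' @return list with `percent`, `n_signal`, `n_tissue` and the two masks.
#' @export
area_fraction <- function(img, signal_channel = "stain",
                          tissue_channel = "tissue", policy = "otsu") {
  stopifnot(inherits(img, "tissue_image"))
  sig <- get_channel(img, signal_channel)
  tis <- get_channel(img, tissue_channel)
  if (is.list(policy) || length(policy) == 2) {
    pol_s <- policy[[1]]; pol_t <- policy[[2]]
  } else pol_s <- pol_t <- policy
  tis_mask <- tis > resolve_threshold(tis, pol_t)
  if (!is.null(img$void_mask)) tis_mask <- tis_mask & !img$void_mask
  if (!any(tis_mask)) stop("empty tissue mask", call. = FALSE)
  sig_mask <- sig > resolve_threshold(sig, pol_s)
  n_t <- sum(tis_mask)
  n_s <- sum(sig_mask & tis_mask)
  list(percent = 100 * n_s / n_t, n_signal = n_s, n_tissue = n_t,
       signal_mask = sig_mask & tis_mask, tissue_mask = tis_mask)
}

# vectorized bilinear interpolation of matrix `m` at fractional pixel
# positions (r, c); NA outside.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  r0 <- pmin(pmax(floor(r[ok]), 1), nr - 1)
  c0 <- pmin(pmax(floor(c[ok]), 1), nc - 1)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  v00 <- m[cbind(r0, c0)];     v01 <- m[cbind(r0, c0 + 1)]
  v10 <- m[cbind(r0 + 1, c0)]; v11 <- m[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
             v10 * fr * (1 - fc) + v11 * fr * fc
  out
}

#' Straighten a curved vessel wall along a spline centerline
#'
#' Fits a cubic spline through the centerline control points
#' (chord-length parameterization; periodic continuation when the first
#' and last points coincide), resamples it uniformly in arc length at one
#' pixel per step, and interpolates every channel on the grid spanned by
#' the arc-length direction (columns) and the signed normal offset
#' (rows). Output rows run from offset `-half_width` (luminal side of the
#' centerline) to `+half_width`.
#'
#' @param img a [tissue_image()].
#' @param centerline data.frame/matrix with `x_um`, `y_um` control points
#'   (>= 4).
#' @param half_width half the straightened band width (um).
#' @return a [tissue_image()] in straightened coordinates; pixels sampled
#'   outside the source image are `NA`. The arc length (um) is attached as
#'   attribute `"arc_length_um"`.
#' @export
straighten_wall <- function(img, centerline, half_width) {
  stopifnot(inherits(img, "tissue_image"))
  cp <- as.matrix(as.data.frame(centerline)[, c(1, 2)])
  if (nrow(cp) < 4) stop("need >= 4 centerline control points", call. = FALSE)
  sc <- img$pixel_scale
  closed <- sqrt(sum((cp[1, ] - cp[nrow(cp), ])^2)) < 1e-9

  if (closed) {
    # periodic continuation: wrap control points on both sides
    base <- cp[-nrow(cp), , drop = FALSE]
    m <- nrow(base)
    ext <- rbind(base[(m - 2):m, , drop = FALSE], base,
                 base[1:3, , drop = FALSE])
    tt <- cumsum(c(0, sqrt(rowSums(diff(ext)^2))))
    fx <- splinefun(tt, ext[, 1], method = "fmm")
    fy <- splinefun(tt, ext[, 2], method = "fmm")
    t0 <- tt[4]; t1 <- tt[4 + m]   # one full period
  } else {
    tt <- cumsum(c(0, sqrt(rowSums(diff(cp)^2))))
    fx <- splinefun(tt, cp[, 1], method = "natural")
    fy <- splinefun(tt, cp[, 2], method = "natural")
    t0 <- tt[1]; t1 <- tt[length(tt)]
  }

  # dense sampling -> arc-length reparameterization
  td <- seq(t0, t1, length.out = max(2000, ceiling((t1 - t0) / sc) * 8))
  xd <- fx(td); yd <- fy(td)
  seg <- sqrt(diff(xd)^2 + diff(yd)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_cols <- max(2L, floor(total / sc) + 1L)
  s_out <- seq(0, total, length.out = n_cols)
  t_of_s <- stats::approx(s, td, xout = s_out, rule = 2)$y
  xs <- fx(t_of_s); ys <- fy(t_of_s)
  dxs <- fx(t_of_s, deriv = 1); dys <- fy(t_of_s, deriv = 1)
  sp <- sqrt(dxs^2 + dys^2)
  tx <- dxs / sp; ty <- dys / sp
  nx <- -ty; ny <- tx

  # curvature guard: normals must not cross inside the band
  dth <- atan2(ty[-1] * tx[-n_cols] - tx[-1] * ty[-n_cols],
               tx[-1] * tx[-n_cols] + ty[-1] * ty[-n_cols])
  ds <- diff(s_out)
  kappa <- abs(dth) / pmax(ds, 1e-12)
  bad <- which(kappa > 1 / half_width)
  if (length(bad) > 0)
    stop(sprintf(paste0("normals self-intersect: curvature radius %.1f um < ",
                        "half width %.1f um near arc position %.1f um"),
                 1 / max(kappa), half_width, s_out[bad[1]]), call. = FALSE)

  offs <- seq(-half_width, half_width, by = sc)
  n_rows <- length(offs)
  straightened <- lapply(img$channels, function(ch) {
    out <- matrix(NA_real_, n_rows, n_cols)
    for (i in seq_len(n_rows)) {
      px <- xs + offs[i] * nx
      py <- ys + offs[i] * ny
      out[i, ] <- bilinear_sample(ch, py / sc + 0.5, px / sc + 0.5)
    }
    out
  })
  res <- tissue_image(straightened, sc)
  attr(res, "arc_length_um") <- total
  res
}

#' Medial thickness profile from a straightened wall
#'
#' Counts tissue-containing pixels in each column of the straightened
#' image (each column is a line perpendicular to the intima) and converts
#' to micrometres. Void and glass pixels are not counted; columns without
#' any medial pixel are excluded.
#'
#' @param straightened a straightened [tissue_image()].
#' @param medial_mask optional logical matrix (same shape) restricting the
#'   count; by default the thresholded tissue channel is used.
#' @param policy threshold policy for the tissue channel when no mask is
#'   given.
#' @return list with `profile_um` (per retained column), `mean`, `sd`,
#'   `range`, `n_columns` and `n_excluded`.
#' @export
medial_thickness <- function(straightened, medial_mask = NULL,
                             policy = "otsu") {
  stopifnot(inherits(straightened, "tissue_image"))
  if (is.null(medial_mask)) {
    tis <- get_channel(straightened, "tissue")
    tisv <- tis
    tisv[is.na(tisv)] <- min(tisv, na.rm = TRUE)
    medial_mask <- tisv > resolve_threshold(tisv, policy) & !is.na(tis)
  }
  if (!any(medial_mask)) stop("empty medial mask", call. = FALSE)
  counts <- colSums(medial_mask, na.rm = TRUE)
  keep <- counts > 0
  if (any(!keep))
    message(sum(!keep), " column(s) without medial pixels excluded")
  prof <- counts[keep] * straightened$pixel_scale
  list(profile_um = prof, mean = mean(prof), sd = sd(prof),
       range = range(prof), n_columns = sum(keep), n_excluded = sum(!keep))
}

#' Regional gelatinase activity from in situ zymography
#'
#' Estimates the fluorescence background as the median of a designated
#' off-tissue area, subtracts it (clipping negatives to zero), and reports
#' the mean background-subtracted fluorescence intensity per square
#' micrometre for each region.
#'
#' @param img a [tissue_image()] with a `fitc` channel.
#' @param regions named list of logical region masks (e.g. analysis strips
#'   or lamellar/inter-lamellar masks).
#' @param background either a numeric background level, a logical mask of
#'   off-tissue pixels, or a list `list(rows =, cols =)` describing an
#'   off-tissue rectangle.
#' @return data.frame with `region`, `mean_intensity_per_um2`, `n_px`,
#'   `area_um2`; the background used is attached as attribute
#'   `"background"`.
#' @export
regional_gelatinase <- function(img, regions, background) {
  stopifnot(inherits(img, "tissue_image"))
  fitc <- get_channel(img, "fitc")
  if (is.numeric(background) && length(background) == 1) {
    bg <- background
  } else if (is.logical(background)) {
    bg <- median(fitc[background])
  } else if (is.list(background)) {
    bg <- median(fitc[background$rows, background$cols])
  } else stop("invalid background specification", call. = FALSE)
  corr <- pmax(fitc - bg, 0)
  px_area <- img$pixel_scale^2
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    if (!identical(dim(m), dim(fitc)))
      stop("region '", nm, "' outside image / shape mismatch", call. = FALSE)
    if (!any(m)) stop("region '", nm, "' is empty", call. = FALSE)
    data.frame(region = nm,
               mean_intensity_per_um2 = mean(corr[m]) / px_area,
               n_px = sum(m), area_um2 = sum(m) * px_area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "background") <- bg
  out
}

#' Split a wall mask into analysis strips
#'
#' Partitions the columns of a (straightened) image into consecutive
#' strips of fixed width, each spanning the wall depth: the standard
#' region layout for zymography quantification.
#'
#' @param mask logical matrix (e.g. tissue mask of a straightened wall).
#' @param strip_width_px strip width in pixels.
#' @param n_strips maximum number of strips (default: as many as fit).
#' @return named list of logical masks `strip_1`, `strip_2`, ...
#' @export
region_strips <- function(mask, strip_width_px = 100, n_strips = NULL) {
  nc <- ncol(mask)
  n_fit <- nc %/% strip_width_px
  if (n_fit < 1) stop("mask narrower than one strip", call. = FALSE)
  n <- min(n_fit, n_strips %||% n_fit)
  out <- list()
  for (i in seq_len(n)) {
    cols <- ((i - 1) * strip_width_px + 1):(i * strip_width_px)
    m <- matrix(FALSE, nrow(mask), nc)
    m[, cols] <- mask[, cols]
    out[[paste0("strip_", i)]] <- m
  }
  out
}
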