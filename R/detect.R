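#' Detect bead centroids in a height image
#'
#' Beads are local height maxima of the Gaussian-smoothed image. A pixel
#' qualifies when it is at least as high as its 8 neighbours, lies outside
#' the exclusion mask, and stands at least `min_prominence` above the
#' robust image background (the median of the smoothed image). Qualifying
#' maxima are accepted in order of decreasing height subject to a minimum
#' pairwise separation, then refined to sub-pixel centroids by an
#' intensity-weighted centre of mass over a 5x5 window.
#'
#' @param img a [height_image()], typically flattened.
#' @param mask optional logical exclusion matrix (`TRUE` = excluded),
#'   combined with `img$mask`.
#' @param smoothing_sigma Gaussian smoothing sigma in nm; values below the
#'   pixel scale are clamped to it (with a warning).
#' @param min_prominence minimum height above the smoothed-image median
#'   (height units).
#' @param min_separation minimum distance between accepted beads (nm); must
#'   be at least two pixels.
#' @param polarity `"bright"` when beads are maxima (the native height
#'   convention) or `"dark"` for a contrast-inverted image.
#' @return data.frame with columns `x_nm`, `y_nm` (sub-pixel centroids),
#'   `row`, `col` (1-based peak pixel) and `height` (smoothed peak height).
#' @export
detect_beads <- function(img, mask = NULL, smoothing_sigma = 6,
                         min_prominence = 3, min_separation = 30,
                         polarity = c("bright", "dark")) {
  stopifnot(inherits(img, "height_image"))
  polarity <- match.arg(polarity)
  scale <- img$pixel_scale
  if (min_separation < 2 * scale)
    stop("min_separation must be >= 2 pixels", call. = FALSE)
  if (smoothing_sigma < scale) {
    warning("smoothing_sigma below pixel scale; clamped to ", scale, " nm")
    smoothing_sigma <- scale
  }
  v <- img$values
  if (polarity == "dark") v <- 2 * median(v) - v
  excl <- img$mask
  if (!is.null(mask)) excl <- if (is.null(excl)) mask else (excl | mask)

  sm <- ebimage_gblur(v, smoothing_sigma / scale)
  bg <- median(sm)

  peaks <- local_maxima_8(sm)
  if (!is.null(excl)) peaks <- peaks & !excl
  peaks <- peaks & (sm >= bg + min_prominence)
  idx <- which(peaks, arr.ind = TRUE)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      row = integer(0), col = integer(0),
                      height = numeric(0))
  if (nrow(idx) == 0) return(empty)

  h <- sm[idx]
  ord <- order(-h, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  h <- h[ord]
  sep_px2 <- (min_separation / scale)^2
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1L)])
    d2 <- (idx[prev, 1] - idx[i, 1])^2 + (idx[prev, 2] - idx[i, 2])^2
    keep[i] <- all(d2 >= sep_px2)
  }
  idx <- idx[keep, , drop = FALSE]
  h <- h[keep]

  # sub-pixel refinement: centre of mass of the background-subtracted 5x5
  # neighbourhood of the smoothed image
  n <- nrow(idx)
  cr <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rr <- max(1, r - 2):min(nrow(sm), r + 2)
    ccw <- max(1, c - 2):min(ncol(sm), c + 2)
    w <- sm[rr, ccw, drop = FALSE]
    w <- w - min(w)
    tw <- sum(w)
    if (tw <= 0) { cr[i] <- r; cc[i] <- c; next }
    cr[i] <- sum(rowSums(w) * rr) / tw
    cc[i] <- sum(colSums(w) * ccw) / tw
  }
  out <- data.frame(x_nm = px_to_nm(cc, scale), y_nm = px_to_nm(cr, scale),
                    row = idx[, 1], col = idx[, 2], height = h)
  out[order(out$row, out$col), , drop = FALSE]
}

# 8-neighbourhood local maxima (>= all neighbours), computed by comparing
# against shifted copies padded with -Inf.
local_maxima_8 <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- v[rs - dr, cs - dc, drop = FALSE]
    out
  }
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (v >= shift(dr, dc))
  }
  res
}

# Gaussian blur through EBImage; preserves the matrix orientation.
ebimage_gblur <- function(v, sigma_px) {
  if (sigma_px <= 0) return(v)
  as.matrix(EBImage::gblur(v, sigma = sigma_px))
}
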