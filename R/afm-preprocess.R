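#' Line-by-line scanline compensation
#'
#' Scanning-probe images carry per-scanline height offsets (and sometimes
#' tilts) from piezo drift. Flattening subtracts a robust per-row baseline:
#' order 0 removes the row median; order 1 removes a robust linear tilt
#' (M-estimation, Huber) and then re-centres the residual row median at
#' zero. Pixels flagged in `img$mask` (or in `exclude`) are ignored when
#' estimating the baseline but are still corrected.
#'
#' @param img a [height_image()].
#' @param order 0 (offset only) or 1 (offset + tilt).
#' @param exclude optional logical matrix of pixels to ignore during
#'   baseline estimation (combined with `img$mask`).
#' @return flattened [height_image()]; every row of the output has median
#'   ~0 over the non-excluded pixels.
#' @export
flatten_scanlines <- function(img, order = 0, exclude = NULL) {
  stopifnot(inherits(img, "height_image"))
  if (!order %in% c(0, 1)) stop("order must be 0 or 1", call. = FALSE)
  v <- img$values
  nc <- ncol(v)
  if (nc < order + 1) stop("rows shorter than order + 1 pixels", call. = FALSE)
  excl <- img$mask
  if (!is.null(exclude)) {
    excl <- if (is.null(excl)) exclude else (excl | exclude)
  }
  xs <- seq_len(nc)
  for (r in seq_len(nrow(v))) {
    row <- v[r, ]
    use <- if (is.null(excl)) rep(TRUE, nc) else !excl[r, ]
    if (sum(use) < order + 1) use <- rep(TRUE, nc)  # fully excluded row
    if (order == 1 && sum(use) >= 4) {
      fit <- tryCatch(
        suppressWarnings(MASS::rlm(row[use] ~ xs[use], maxit = 50)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- coef(fit)
        row <- row - (cf[1] + cf[2] * xs)
      }
    }
    v[r, ] <- row - median(row[use])
  }
  height_image(v, img$pixel_scale, img$mask)
}

#' Identify large bright artifacts for exclusion
#'
#' Surface impurities appear as bright blobs far larger than a bead. Pixels
#' above `median + z_threshold * robust sigma` (sigma from the median
#' absolute deviation) are grouped into connected components; components
#' whose area exceeds `min_blob_area` are flagged. The returned mask is
#' `TRUE` on excluded pixels and can be attached to the image or passed to
#' [detect_beads()].
#'
#' @param img a [height_image()] (typically after a first flattening pass).
#' @param z_threshold robust-sigma multiple (> 0).
#' @param min_blob_area minimum component area in pixels to count as an
#'   artifact (beads cover far fewer pixels).
#' @return logical matrix, `TRUE` = excluded; may be all-`FALSE`.
#' @export
mask_artifacts <- function(img, z_threshold = 5, min_blob_area = 150) {
  stopifnot(inherits(img, "height_image"))
  if (z_threshold <= 0) stop("z_threshold must be > 0", call. = FALSE)
  v <- img$values
  s <- mad(v)
  if (s == 0) s <- sd(v)
  if (is.na(s) || s == 0)  # uniform (e.g. saturated) frame: no usable signal
    return(matrix(TRUE, nrow(v), ncol(v)))
  bright <- v > median(v) + z_threshold * s
  if (!any(bright)) return(matrix(FALSE, nrow(v), ncol(v)))
  if (mean(bright) > 0.9) return(matrix(TRUE, nrow(v), ncol(v)))
  lab <- EBImage::bwlabel(bright)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas > min_blob_area)
  mask <- matrix(lab %in% keep, nrow(v), ncol(v))
  mask
}

#' Invert image contrast about the median
#'
#' Reflects heights about the image median so that beads appear dark on a
#' light background (the display convention of the original analysis).
#' Extrema change polarity; positions are unchanged, and applying the
#' inversion twice restores the image.
#'
#' @param img a [height_image()].
#' @return inverted [height_image()].
#' @export
invert_contrast <- function(img) {
  stopifnot(inherits(img, "height_image"))
  m <- median(img$values)
  height_image(2 * m - img$values, img$pixel_scale, img$mask)
}
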