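#' Multi-channel tissue-section images
#'
#' A `tissue_image` bundles named co-registered 2-D channels (e.g.
#' `tissue` for the thresholdable brightfield blue channel, `stain` for the
#' collagen/elastin-positive channel, `fitc` for gelatinase fluorescence,
#' `wavespeed` for an acoustic wave-speed map in m/s) with a physical pixel
#' scale in micrometres per pixel. Pixel (r, c) has its centre at physical
#' coordinates x = (c - 0.5) * pixel_scale, y = (r - 0.5) * pixel_scale;
#' a pixel belongs to a region iff its centre does.
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param void_mask optional logical matrix marking voids/glass to exclude.
#' @return object of class `tissue_image`.
#' @export
tissue_image <- function(channels, pixel_scale, void_mask = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list of matrices", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must be matrices of the same shape", call. = FALSE)
  if (pixel_scale <= 0) stop("pixel_scale must be > 0", call. = FALSE)
  if (!is.null(void_mask) && !identical(dim(void_mask), dims[[1]]))
    stop("void_mask shape mismatch", call. = FALSE)
  structure(list(channels = channels, pixel_scale = as.numeric(pixel_scale),
                 void_mask = void_mask),
            class = "tissue_image")
}

#' @export
print.tissue_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("tissue_image: %d x %d px at %.3g um/px; channels: %s\n",
              d[1], d[2], x$pixel_scale,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(img, name) {
  ch <- img$channels[[name]]
  if (is.null(ch)) stop("channel '", name, "' not present", call. = FALSE)
  ch
}
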