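#' AFM height images
#'
#' A `height_image` is a 2-D raster of surface height with a physical pixel
#' scale. The coordinate convention is row-major with the origin at the
#' top-left pixel: a pixel at (row r, column c), 1-based in R, has physical
#' coordinates x = (c - 1) * pixel_scale, y = (r - 1) * pixel_scale in nm.
#' An optional logical mask marks pixels excluded from analysis.
#'
#' @param values numeric matrix of heights (arbitrary height units).
#' @param pixel_scale nm per pixel (> 0).
#' @param mask optional logical matrix, same shape, `TRUE` = excluded.
#' @return object of class `height_image`.
#' @export
height_image <- function(values, pixel_scale, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0)
    stop("pixel_scale must be a single positive number (nm/px)", call. = FALSE)
  if (length(values) == 0L) stop("empty height raster", call. = FALSE)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values)))
      stop("mask must have the same shape as the raster", call. = FALSE)
    storage.mode(mask) <- "logical"
  }
  structure(list(values = values, pixel_scale = as.numeric(pixel_scale),
                 mask = mask),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("height_image: %d x %d px at %.3g nm/px (%.0f x %.0f nm)\n",
              nrow(x$values), ncol(x$values), x$pixel_scale,
              ncol(x$values) * x$pixel_scale, nrow(x$values) * x$pixel_scale))
  cat(sprintf("  height range [%.3g, %.3g]%s\n", min(x$values), max(x$values),
              if (is.null(x$mask)) "" else
                sprintf(", %d px masked", sum(x$mask))))
  invisible(x)
}

#' @export
dim.height_image <- function(x) dim(x$values)

# physical x/y (nm) of 1-based pixel indices
px_to_nm <- function(idx, pixel_scale) (idx - 1) * pixel_scale
nm_to_px <- function(nm, pixel_scale) nm / pixel_scale + 1

#' Read and write height images
#'
#' Height maps are stored either as whitespace-delimited text matrices or as
#' 16-bit grayscale TIFF. TIFF storage is linearly rescaled to the 16-bit
#' range; the affine transform and the physical pixel scale are kept in a
#' JSON sidecar (`<image>.json`) so the raster round-trips to within
#' quantization error.
#'
#' @param img a [height_image()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   anything else for text), unless `format` is given.
#' @param format `"tiff"` or `"text"`.
#' @return `write_height_image` returns `path` invisibly;
#'   `read_height_image` returns a [height_image()].
#' @export
write_height_image <- function(img, path, format = NULL) {
  stopifnot(inherits(img, "height_image"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  meta <- list(pixel_scale_nm_per_px = img$pixel_scale, format = format)
  if (format == "tiff") {
    lo <- min(img$values); hi <- max(img$values)
    span <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((img$values - lo) / span, path, bits.per.sample = 16L)
    meta$height_offset <- lo
    meta$height_span <- span
  } else {
    write.table(format(img$values, digits = 10), path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param sidecar path to the JSON sidecar; defaults to `<path>.json`.
#' @param pixel_scale pixel scale override (nm/px) when no sidecar exists.
#' @rdname write_height_image
#' @export
read_height_image <- function(path, sidecar = paste0(path, ".json"),
                              pixel_scale = NULL) {
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- pixel_scale %||% meta$pixel_scale_nm_per_px
  if (is.null(scale))
    stop("pixel scale not given and no JSON sidecar found", call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    off <- meta$height_offset %||% 0
    span <- meta$height_span %||% 1
    v <- v * span + off
  } else {
    v <- as.matrix(read.table(path))
    dimnames(v) <- NULL
  }
  height_image(v, as.numeric(scale))
}
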