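#' Measure periodicity and length of linked chains
#'
#' Periodicity is the Euclidean distance between consecutive bead centroids
#' (nm); length is the number of beads per chain (the number of repeats of
#' the beaded structure is one fewer and is reported alongside). Chains
#' with fewer than two beads are excluded.
#'
#' @param chains list of `bead_chain` objects from [link_chains()].
#' @param provenance optional list recording image id and parameters.
#' @return object of class `morphometry_result`: a list with
#'   \describe{
#'     \item{chains}{data.frame `chain_id`, `bead_count`, `n_repeats`,
#'       `mean_repeat_nm`}
#'     \item{periodicities}{pooled numeric vector of repeats (nm)}
#'     \item{provenance}{as given}
#'   }
#' @export
measure_chains <- function(chains, provenance = list()) {
  if (length(chains) == 0)
    return(structure(list(
      chains = data.frame(chain_id = integer(0), bead_count = integer(0),
                          n_repeats = integer(0), mean_repeat_nm = numeric(0)),
      periodicities = numeric(0), provenance = provenance),
      class = "morphometry_result"))
  ok <- vapply(chains, function(ch) ch$bead_count >= 2L, logical(1))
  if (any(!ok))
    message(sum(!ok), " chain(s) with < 2 beads excluded")
  chains <- chains[ok]
  if (length(chains) == 0)
    return(measure_chains(list(), provenance))
  tab <- data.frame(
    chain_id = vapply(chains, `[[`, integer(1), "chain_id"),
    bead_count = vapply(chains, `[[`, integer(1), "bead_count"),
    n_repeats = vapply(chains, function(ch) length(ch$repeats), integer(1)),
    mean_repeat_nm = vapply(chains, function(ch) mean(ch$repeats),
                            numeric(1)))
  pooled <- unlist(lapply(chains, `[[`, "repeats"), use.names = FALSE)
  stopifnot(length(pooled) == sum(tab$bead_count - 1L))
  structure(list(chains = tab, periodicities = pooled,
                 provenance = provenance),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("morphometry_result: %d chains, %d pooled periodicities\n",
              nrow(x$chains), length(x$periodicities)))
  if (nrow(x$chains) > 0)
    cat(sprintf("  mean length %.1f beads; mean periodicity %.1f nm\n",
                mean(x$chains$bead_count), mean(x$periodicities)))
  invisible(x)
}

#' Full AFM morphometry pipeline
#'
#' Runs the complete image-analysis routine on one height image: a first
#' scanline flattening pass, artifact identification, a second flattening
#' pass excluding the flagged pixels from the baseline estimate, bead
#' detection, chain linking, and measurement. The contrast inversion used
#' for display does not affect detection, which operates on a polarity
#' flag.
#'
#' @param img a [height_image()].
#' @param flatten_order per-row baseline order, 0 or 1.
#' @param z_threshold,min_blob_area artifact mask parameters
#'   (see [mask_artifacts()]).
#' @param smoothing_sigma,min_prominence,min_separation,polarity bead
#'   detection parameters (see [detect_beads()]).
#' @param max_link,max_turn chain linking parameters (see [link_chains()]).
#' @param image_id identifier stored in the result's provenance.
#' @return a `morphometry_result` (see [measure_chains()]); the bead table
#'   is attached as attribute `"beads"`.
#' @export
afm_pipeline <- function(img, flatten_order = 0,
                         z_threshold = 5, min_blob_area = 150,
                         smoothing_sigma = 6, min_prominence = 3,
                         min_separation = 30, polarity = "bright",
                         max_link = 125, max_turn = 60,
                         image_id = NA) {
  flat1 <- flatten_scanlines(img, order = flatten_order)
  mask <- mask_artifacts(flat1, z_threshold, min_blob_area)
  flat2 <- flatten_scanlines(img, order = flatten_order, exclude = mask)
  beads <- detect_beads(flat2, mask = mask,
                        smoothing_sigma = smoothing_sigma,
                        min_prominence = min_prominence,
                        min_separation = min_separation,
                        polarity = polarity)
  chains <- link_chains(beads, max_link = max_link, max_turn = max_turn)
  res <- measure_chains(chains, provenance = list(
    image_id = image_id, flatten_order = flatten_order,
    smoothing_sigma = smoothing_sigma, min_prominence = min_prominence,
    min_separation = min_separation, max_link = max_link,
    max_turn = max_turn))
  attr(res, "beads") <- beads
  res
}
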