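#' Lorentzian periodicity distribution presets
#'
#' A preset describes the bead-to-bead repeat (periodicity) distribution of a
#' population of fibrillin microfibrils as a mixture of one or two truncated
#' Lorentzian (Cauchy) peaks. Each component has a centre `x0` (nm), a
#' half-width at half maximum `gamma` (nm) and a mixing weight; values are
#' truncated to a plausible physical range of beaded repeats.
#'
#' @param centres numeric vector of component centres (nm).
#' @param gammas numeric vector of half-widths at half maximum (nm), recycled
#'   to the number of components.
#' @param weights mixing weights; must sum to 1.
#' @param trunc length-2 numeric, lower/upper truncation bounds (nm).
#' @param label group label carried through downstream tables.
#' @return An object of class `lorentz_preset`.
#' @examples
#' control_preset()
#' diabetic_preset()
#' @export
lorentz_preset <- function(centres, gammas, weights = NULL,
                           trunc = c(30, 120), label = "sample") {
  k <- length(centres)
  gammas <- rep_len(gammas, k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k)
    stop("need one weight per component", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("component weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(gammas <= 0)) stop("half-widths must be > 0", call. = FALSE)
  if (length(trunc) != 2L || trunc[1] >= trunc[2])
    stop("trunc must be an increasing length-2 range", call. = FALSE)
  if (any(centres < trunc[1] | centres > trunc[2]))
    stop("centres must lie within the truncation bounds", call. = FALSE)
  structure(
    list(centres = as.numeric(centres), gammas = as.numeric(gammas),
         weights = as.numeric(weights), trunc = as.numeric(trunc),
         label = label),
    class = "lorentz_preset")
}

#' @export
print.lorentz_preset <- function(x, ...) {
  cat("Lorentzian periodicity preset '", x$label, "'\n", sep = "")
  for (i in seq_along(x$centres))
    cat(sprintf("  component %d: centre %.1f nm, HWHM %.1f nm, weight %.2f\n",
                i, x$centres[i], x$gammas[i], x$weights[i]))
  cat(sprintf("  truncated to [%.0f, %.0f] nm\n", x$trunc[1], x$trunc[2]))
  invisible(x)
}

#' @describeIn lorentz_preset healthy (control) aorta: single peak at 56 nm,
#'   the canonical untensioned microfibril repeat.
#' @export
control_preset <- function() {
  lorentz_preset(56, 3, 1, label = "control")
}

#' @describeIn lorentz_preset diabetic aorta: two populations with resting
#'   repeats at 51 and 73 nm (lower/upper weights 0.7/0.3).
#' @export
diabetic_preset <- function() {
  lorentz_preset(c(51, 73), c(3, 3), c(0.7, 0.3), label = "diabetic")
}

#' @describeIn lorentz_preset post-combing (tensioned) presets; mass is
#'   shifted towards and above 60 nm relative to the untensioned state.
#' @param group `"control"` or `"diabetic"` for `combed_preset()`.
#' @export
combed_preset <- function(group = c("control", "diabetic")) {
  group <- match.arg(group)
  if (group == "control")
    lorentz_preset(58, 6, 1, label = "control_combed")
  else
    lorentz_preset(c(55, 66), c(5, 6), c(0.45, 0.55), label = "diabetic_combed")
}

#' Microfibril chain-length presets
#'
#' Mean and standard deviation of bead counts per microfibril for the two
#' study groups (control 21, SD 13; diabetic 18, SD 19 beads).
#'
#' @param group `"control"` or `"diabetic"`.
#' @return list with `mean`, `sd` (beads) and `label`.
#' @export
chain_length_preset <- function(group = c("control", "diabetic")) {
  group <- match.arg(group)
  if (group == "control") list(mean = 21, sd = 13, label = "control")
  else list(mean = 18, sd = 19, label = "diabetic")
}
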