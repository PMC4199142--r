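#' Periodicity samples
#'
#' A `periodicity_sample` is a labelled vector of bead-to-bead distances (nm)
#' for one group (optionally one animal), in either the untensioned or the
#' combed (tensioned) state.
#'
#' @param values positive numeric vector of periodicities (nm).
#' @param group group label.
#' @param animal optional animal identifier.
#' @param state `"untensioned"` or `"combed"`.
#' @return An object of class `periodicity_sample` (a numeric vector with
#'   `group`, `animal` and `state` attributes).
#' @export
periodicity_sample <- function(values, group = "sample", animal = NA,
                               state = c("untensioned", "combed")) {
  state <- match.arg(state)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty periodicity sample", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("periodicities must be positive and finite", call. = FALSE)
  structure(values, group = group, animal = animal, state = state,
            class = "periodicity_sample")
}

#' @export
print.periodicity_sample <- function(x, ...) {
  cat(sprintf("periodicity_sample: n = %d, group = %s, state = %s\n",
              length(x), attr(x, "group"), attr(x, "state")))
  cat(sprintf("  median %.1f nm, IQR [%.1f, %.1f] nm\n",
              median(unclass(x)), quantile(unclass(x), .25),
              quantile(unclass(x), .75)))
  invisible(x)
}

#' Draw periodicity values from a Lorentzian preset
#'
#' Samples bead-to-bead repeat distances from the (mixture of) truncated
#' Lorentzian components of a preset. Components are chosen by their mixing
#' weights; values falling outside the truncation bounds are re-drawn from
#' the same component (rejection truncation).
#'
#' @param preset a [lorentz_preset()].
#' @param n number of values to draw (>= 1).
#' @param seed optional integer seed; a fixed seed gives bit-identical
#'   samples without disturbing the caller's RNG stream.
#' @return A [periodicity_sample()] of length `n` with a `component`
#'   attribute recording the true component of each draw.
#' @examples
#' x <- sample_periodicities(control_preset(), 500, seed = 1)
#' median(x)
#' @export
sample_periodicities <- function(preset, n, seed = NULL) {
  stopifnot(inherits(preset, "lorentz_preset"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    k <- length(preset$centres)
    comp <- if (k == 1L) rep(1L, n)
            else sample.int(k, n, replace = TRUE, prob = preset$weights)
    x <- rcauchy(n, preset$centres[comp], preset$gammas[comp])
    bad <- x < preset$trunc[1] | x > preset$trunc[2]
    while (any(bad)) {
      x[bad] <- rcauchy(sum(bad), preset$centres[comp[bad]],
                        preset$gammas[comp[bad]])
      bad <- x < preset$trunc[1] | x > preset$trunc[2]
    }
    out <- periodicity_sample(x, group = preset$label)
    attr(out, "component") <- comp
    out
  })
}

#' Draw microfibril chain lengths (bead counts)
#'
#' Bead counts per microfibril are right-skewed: group standard deviations
#' comparable to (or exceeding) the mean are only possible for a positively
#' skewed positive distribution. Lengths are drawn from a log-normal
#' distribution moment-matched to the requested mean and SD, rounded to
#' integers, and rejection-truncated to >= 2 beads (a chain needs two beads
#' to define a repeat).
#'
#' @param mean target mean bead count (>= 2).
#' @param sd target standard deviation of bead counts (> 0); `sd = 0` gives
#'   the degenerate constant `round(mean)`.
#' @param n number of chains.
#' @param seed optional integer seed.
#' @return integer vector of bead counts, all >= 2.
#' @examples
#' sample_chain_lengths(21, 13, 10, seed = 1)
#' @export
sample_chain_lengths <- function(mean, sd, n, seed = NULL) {
  if (!is.numeric(mean) || mean < 2)
    stop("mean bead count must be >= 2", call. = FALSE)
  if (!is.numeric(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (sd == 0) return(rep(max(2L, as.integer(round(mean))), n))
  sig2 <- log(1 + sd^2 / mean^2)
  mu <- log(mean) - sig2 / 2
  with_seed(seed, {
    x <- as.integer(round(rlnorm(n, mu, sqrt(sig2))))
    bad <- x < 2L
    while (any(bad)) {
      x[bad] <- as.integer(round(rlnorm(sum(bad), mu, sqrt(sig2))))
      bad <- x < 2L
    }
    x
  })
}

# Mixture density of a preset on the untruncated scale (used by tests and
# for histogram overlays).
dlorentz_mix <- function(x, preset) {
  d <- 0
  for (i in seq_along(preset$centres))
    d <- d + preset$weights[i] *
      stats::dcauchy(x, preset$centres[i], preset$gammas[i])
  d
}
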