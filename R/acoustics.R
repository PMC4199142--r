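#' Longitudinal wave speed and Young's modulus conversion
#'
#' For an isotropic material the longitudinal acoustic wave speed is
#' \deqn{v_L = \sqrt{C_{11} / \rho}, \qquad
#'       C_{11} = E (1 - \nu) / ((1 + \nu)(1 - 2\nu))}
#' with Young's modulus `E` (Pa), mass density `rho` (kg/m^3) and
#' Poisson's ratio `nu`. A higher wave speed therefore indicates a stiffer
#' material; `modulus_from_wave_speed()` is the algebraic inverse.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param rho mass density (kg/m^3), > 0.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return `wave_speed_from_modulus`: wave speed (m/s);
#'   `modulus_from_wave_speed`: Young's modulus (Pa).
#' @examples
#' wave_speed_from_modulus(1e9, 1000, 0)   # 1000 m/s
#' @export
wave_speed_from_modulus <- function(E, rho, nu = 0) {
  check_acoustic(E, rho, nu)
  c11 <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  sqrt(c11 / rho)
}

#' @param v_L longitudinal wave speed (m/s), > 0.
#' @rdname wave_speed_from_modulus
#' @export
modulus_from_wave_speed <- function(v_L, rho, nu = 0) {
  if (any(v_L <= 0)) stop("wave speed must be > 0", call. = FALSE)
  check_acoustic(1, rho, nu)
  c11 <- rho * v_L^2
  c11 * (1 + nu) * (1 - 2 * nu) / (1 - nu)
}

check_acoustic <- function(E, rho, nu) {
  if (any(E <= 0)) stop("Young's modulus must be > 0", call. = FALSE)
  if (any(rho <= 0)) stop("density must be > 0", call. = FALSE)
  if (any(nu <= -1 | nu >= 0.5))
    stop("Poisson's ratio must lie in (-1, 0.5)", call. = FALSE)
  invisible(TRUE)
}

#' Per-region wave-speed statistics from an acoustic map
#'
#' Extracts the wave-speed values under each region mask and reports mean,
#' SD, SEM and n, together with a modality call (one vs two peaks) made by
#' [select_modality()] on the region's value distribution. Degenerate
#' (zero-variance) regions are reported as unimodal.
#'
#' @param map numeric matrix of wave speeds (m/s) or a [tissue_image()]
#'   with a `wavespeed` channel.
#' @param regions named list of disjoint, non-empty logical masks.
#' @param bin_width histogram bin width (m/s) for the modality call.
#' @return list with `summary` (data.frame: region, mean, sd, sem, n,
#'   modality) and `values` (named list of per-region samples).
#' @export
region_wave_speed_stats <- function(map, regions, bin_width = 10) {
  if (inherits(map, "tissue_image")) map <- get_channel(map, "wavespeed")
  stopifnot(is.matrix(map))
  nm <- names(regions)
  if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
  overlap <- Reduce(`+`, lapply(regions, function(m) m * 1L))
  if (any(overlap > 1L)) stop("region masks must be disjoint", call. = FALSE)
  vals <- list(); rows <- list()
  for (i in seq_along(regions)) {
    m <- regions[[i]]
    if (!any(m)) stop("region '", nm[i], "' is empty", call. = FALSE)
    v <- map[m]
    modality <- if (length(v) < 50 || sd(v) < .Machine$double.eps^0.5) 1L
    else tryCatch(as.integer(select_modality(v, bin_width = bin_width)),
                  error = function(e) NA_integer_)
    sm <- summarize_sample(v)
    rows[[i]] <- data.frame(region = nm[i], mean = sm$mean, sd = sm$sd,
                            sem = sm$sem, n = sm$n, modality = modality,
                            stringsAsFactors = FALSE)
    vals[[nm[i]]] <- v
  }
  list(summary = do.call(rbind, rows), values = vals)
}
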