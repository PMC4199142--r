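# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results with naive loops so they
# share no code with the package's vectorized implementations.

# Naive truncated-Gaussian convolution (explicit loops, zero-padded).
brute_smooth <- function(v, sigma_px) {
  if (sigma_px <= 0) return(v)
  rad <- max(1L, ceiling(3 * sigma_px))
  off <- -rad:rad
  k <- exp(-off^2 / (2 * sigma_px^2))
  k2 <- outer(k, k)
  k2 <- k2 / sum(k2)
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0; wsum <- 0
    for (i in seq_along(off)) for (j in seq_along(off)) {
      rr <- r + off[i]; cc <- c + off[j]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        acc <- acc + k2[i, j] * v[rr, cc]
        wsum <- wsum + k2[i, j]
      }
    }
    out[r, c] <- acc / wsum
  }
  out
}

# Exhaustive scan for qualifying local maxima: >= all 8 neighbours,
# above median + prominence, greedy minimum separation by descending
# height (ties by row then column). Returns peak pixel indices.
brute_force_maxima <- function(sm, min_prominence, min_sep_px) {
  nr <- nrow(sm); nc <- ncol(sm)
  bg <- median(sm)
  cand <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ok <- sm[r, c] >= bg + min_prominence
    if (!ok) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          sm[rr, cc] > sm[r, c]) ok <- FALSE
    }
    if (ok) cand <- rbind(cand, c(r, c, sm[r, c]))
  }
  if (is.null(cand)) return(matrix(numeric(0), 0, 2))
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (nrow(kept) > 0)
      for (j in seq_len(nrow(kept)))
        if ((kept[j, 1] - cand[i, 1])^2 + (kept[j, 2] - cand[i, 2])^2 <
            min_sep_px^2) { ok <- FALSE; break }
    if (ok) kept <- rbind(kept, cand[i, 1:2])
  }
  kept
}

# Match detected centroids (nm) against ground-truth bead positions;
# returns the distance from each truth bead to its nearest detection.
match_distances <- function(detected, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((detected$x_nm - truth$x_nm[i])^2 +
             (detected$y_nm - truth$y_nm[i])^2)),
    numeric(1))
}

# Near-degenerate single-spacing preset (gamma ~ 0) for exact-geometry
# fixtures.
delta_preset <- function(centre = 56) {
  lorentz_preset(centre, 1e-6, 1, label = "delta")
}

quiet_config <- function(...) {
  chain_render_config(noise_sd = 0, scanline_offset_sd = 0,
                      artifact_density = 0, ...)
}
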