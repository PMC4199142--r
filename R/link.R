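#' Link detected beads into chains
#'
#' Beads are joined greedily, shortest candidate link first. A link between
#' two beads is admitted only if (i) its length is at most `max_link`,
#' (ii) neither bead already has two links, (iii) it does not close a
#' cycle, and (iv) at either endpoint that already has a link, the turn
#' angle between the existing link and the new one is at most `max_turn`.
#' Ties in link length are broken by bead index (smaller first), making the
#' result deterministic. Chains are returned ordered end-to-end; beads left
#' unlinked (singletons) are discarded.
#'
#' @param beads bead table from [detect_beads()] (needs `x_nm`, `y_nm`).
#' @param max_link maximum bead-to-bead link length (nm). The default,
#'   125 nm, slightly exceeds the largest physically plausible repeat so a
#'   heavy-tailed spacing or a single missed bead does not break a chain.
#' @param max_turn maximum turn angle between consecutive links (degrees).
#' @return list of `bead_chain` objects; each is a list with `chain_id`,
#'   `beads` (ordered data.frame `x_nm`, `y_nm`), `repeats` (consecutive
#'   distances, nm) and `bead_count`.
#' @export
link_chains <- function(beads, max_link = 125, max_turn = 60) {
  if (max_link <= 0) stop("max_link must be > 0", call. = FALSE)
  n <- nrow(beads)
  if (is.null(n) || n == 0) return(list())
  x <- beads$x_nm; y <- beads$y_nm
  # candidate pairs within max_link
  cand <- NULL
  if (n > 1) {
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    d <- sqrt(dx^2 + dy^2)
    pair <- which(upper.tri(d) & d <= max_link, arr.ind = TRUE)
    if (nrow(pair) > 0) {
      cand <- data.frame(i = pair[, 1], j = pair[, 2],
                         d = d[pair])
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
    }
  }
  links <- vector("list", n)        # up to 2 partner indices per bead
  parent <- seq_len(n)              # union-find
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  cos_min <- cos(pi - max_turn * pi / 180)  # admissible cos(angle at vertex)

  turn_ok <- function(a, b) {
    # at vertex a with existing partner p, angle between (a->p) and (a->b)
    # must be >= 180 - max_turn, i.e. cos(angle) <= cos(180 - max_turn)
    for (p in links[[a]]) {
      v1 <- c(x[p] - x[a], y[p] - y[a])
      v2 <- c(x[b] - x[a], y[b] - y[a])
      cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      if (cs > cos_min + 1e-12) return(FALSE)
    }
    TRUE
  }

  if (!is.null(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (length(links[[i]]) >= 2L || length(links[[j]]) >= 2L) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next                      # would close a cycle
      if (!turn_ok(i, j) || !turn_ok(j, i)) next
      links[[i]] <- c(links[[i]], j)
      links[[j]] <- c(links[[j]], i)
      parent[ri] <- rj
    }
  }

  deg <- lengths(links)
  visited <- logical(n)
  chains <- list()
  trace_path <- function(start) {
    path <- start
    visited[start] <<- TRUE
    prev <- 0L
    cur <- start
    repeat {
      nxt <- setdiff(links[[cur]], prev)
      if (length(nxt) == 0L) break
      nxt <- nxt[1]
      path <- c(path, nxt)
      visited[nxt] <<- TRUE
      prev <- cur; cur <- nxt
    }
    path
  }
  for (s in which(deg == 1L)) {
    if (visited[s]) next
    path <- trace_path(s)
    chains[[length(chains) + 1L]] <- path
  }

  out <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    p <- chains[[ci]]
    b <- data.frame(x_nm = x[p], y_nm = y[p])
    out[[ci]] <- structure(
      list(chain_id = ci, beads = b,
           repeats = sqrt(diff(b$x_nm)^2 + diff(b$y_nm)^2),
           bead_count = length(p)),
      class = "bead_chain")
  }
  out
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("bead_chain %d: %d beads, %d repeats, mean repeat %.1f nm\n",
              x$chain_id, x$bead_count, length(x$repeats),
              mean(x$repeats)))
  invisible(x)
}
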