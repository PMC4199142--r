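#' Read and write periodicity tables
#'
#' Periodicity tables are flat CSV files with columns `value_nm`, `group`,
#' `animal`, `state`; each (group, animal, state) combination becomes one
#' [periodicity_sample()].
#'
#' @param samples a [periodicity_sample()] or a list of them.
#' @param path CSV path.
#' @return `write_periodicity_csv` returns `path` invisibly;
#'   `read_periodicity_csv` returns a list of [periodicity_sample()].
#' @export
write_periodicity_csv <- function(samples, path) {
  if (inherits(samples, "periodicity_sample")) samples <- list(samples)
  tab <- do.call(rbind, lapply(samples, function(s)
    data.frame(value_nm = as.numeric(s), group = attr(s, "group"),
               animal = attr(s, "animal"), state = attr(s, "state"),
               stringsAsFactors = FALSE)))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_periodicity_csv
#' @export
read_periodicity_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("value_nm", "group")
  if (!all(need %in% names(tab)))
    stop("periodicity CSV needs columns value_nm and group", call. = FALSE)
  if (is.null(tab$animal)) tab$animal <- NA
  if (is.null(tab$state)) tab$state <- "untensioned"
  key <- paste(tab$group, tab$animal, tab$state, sep = "\r")
  lapply(split(tab, key), function(d)
    periodicity_sample(d$value_nm, group = d$group[1], animal = d$animal[1],
                       state = d$state[1]))
}

#' Write a ground-truth bead table as CSV
#'
#' @param truth result of [render_chain_image()] (or its `beads` element).
#' @param path CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  beads <- if (is.data.frame(truth)) truth else truth$beads
  write.csv(beads[, c("chain_id", "bead_idx", "x_nm", "y_nm")], path,
            row.names = FALSE)
  invisible(path)
}

#' Serialize fit results and comparisons as JSON
#'
#' @param x a `lorentz_fit`, `comparison_result`, or any list of plain
#'   values.
#' @param path JSON path.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "lorentz_fit"))
    x <- x[c("k", "centres", "gammas", "amplitudes", "r_squared",
             "bin_width", "aic")]
  if (inherits(x, "comparison_result")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
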