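#' Fraction of repeats above a threshold
#'
#' Proportion of periodicity values strictly greater than `threshold`, with
#' a Wilson 95% binomial confidence interval. Used to quantify the extended
#' sub-population (e.g. repeats beyond 65 nm at rest, or beyond 60 nm after
#' molecular combing).
#'
#' @param sample a [periodicity_sample()] or numeric vector.
#' @param threshold threshold (nm), > 0.
#' @param conf confidence level for the Wilson interval.
#' @return list with `fraction`, `n_above`, `n`, `ci` (length-2) and
#'   `threshold`.
#' @examples
#' fraction_above(c(50, 60, 70), 65)$fraction
#' @export
fraction_above <- function(sample, threshold, conf = 0.95) {
  x <- as.numeric(sample)
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  n <- length(x)
  s <- sum(x > threshold)
  p <- s / n
  z <- qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  cen <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(fraction = p, n_above = s, n = n,
       ci = c(max(0, cen - hw), min(1, cen + hw)), threshold = threshold)
}

#' Nonparametric comparison of periodicity samples
#'
#' Dispatches to the named two-sided nonparametric test: Mann-Whitney U
#' (`wilcox.test`), two-sample Kolmogorov-Smirnov (`ks.test`) or
#' Kruskal-Wallis (`kruskal.test`, which accepts three or more samples
#' passed as a list in `a`).
#'
#' @param a first sample, or a list of >= 3 samples for Kruskal-Wallis.
#' @param b second sample (ignored for a list input).
#' @param test `"mann_whitney"`, `"ks"` or `"kruskal_wallis"`.
#' @return object of class `comparison_result`: list with `test`,
#'   `statistic`, `p_value` and `group_sizes`.
#' @examples
#' x <- sample_periodicities(control_preset(), 200, seed = 1)
#' y <- sample_periodicities(diabetic_preset(), 200, seed = 2)
#' compare_samples(x, y, "ks")
#' @export
compare_samples <- function(a, b = NULL,
                            test = c("mann_whitney", "ks", "kruskal_wallis")) {
  if (length(test) != 1 || !test %in% c("mann_whitney", "ks", "kruskal_wallis"))
    stop("unknown test name: ", paste(test, collapse = "/"), call. = FALSE)
  if (test == "kruskal_wallis") {
    groups <- if (is.list(a) && !inherits(a, "periodicity_sample")) a
              else list(a, b)
    groups <- lapply(groups, as.numeric)
    if (any(lengths(groups) == 0)) stop("empty sample", call. = FALSE)
    ht <- kruskal.test(groups)
    sizes <- lengths(groups)
  } else {
    av <- as.numeric(a); bv <- as.numeric(b)
    if (length(av) == 0 || length(bv) == 0)
      stop("empty sample", call. = FALSE)
    ht <- if (test == "mann_whitney")
      suppressWarnings(wilcox.test(av, bv, alternative = "two.sided"))
    else
      suppressWarnings(ks.test(av, bv, alternative = "two.sided"))
    sizes <- c(length(av), length(bv))
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, group_sizes = sizes),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n = %s)\n", x$test,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Summary statistics in mean +/- SEM form
#'
#' Mean, standard deviation (n - 1 denominator), standard error of the mean
#' and n, with a `"mean +/- SEM"` display string rounded to the SEM's
#' leading digit. For a single value the SD and SEM are reported as
#' missing.
#'
#' @param x numeric vector or [periodicity_sample()].
#' @param digits digits used in the display string.
#' @return data.frame with columns `mean`, `sd`, `sem`, `n`, `label`.
#' @examples
#' summarize_sample(c(1, 2, 3))
#' @export
summarize_sample <- function(x, digits = NULL) {
  v <- as.numeric(x)
  if (length(v) == 0) stop("empty sample", call. = FALSE)
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1) sd(v) else NA_real_
  sem <- if (n > 1) s / sqrt(n) else NA_real_
  lab <- if (is.na(sem)) sprintf("%g (n = 1)", m) else {
    d <- digits %||% if (sem > 0) max(0, -floor(log10(sem))) else 0
    sprintf("%s ± %s", formatC(round(m, d), format = "f", digits = d),
            formatC(round(sem, d), format = "f", digits = d))
  }
  data.frame(mean = m, sd = s, sem = sem, n = n, label = lab,
             stringsAsFactors = FALSE)
}

#' Per-animal and pooled summaries of a set of periodicity samples
#'
#' @param samples list of [periodicity_sample()] objects.
#' @return data.frame with one row per sample (labelled by group/animal)
#'   plus one pooled row per group.
#' @export
summarize_samples <- function(samples) {
  rows <- lapply(samples, function(s) {
    cbind(group = attr(s, "group"), animal = attr(s, "animal"),
          summarize_sample(s))
  })
  per <- do.call(rbind, rows)
  pooled <- lapply(split(samples, vapply(samples, attr, "", "group")),
                   function(g) {
                     s <- unlist(lapply(g, as.numeric))
                     cbind(group = attr(g[[1]], "group"), animal = "pooled",
                           summarize_sample(s))
                   })
  rbind(per, do.call(rbind, pooled))
}
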