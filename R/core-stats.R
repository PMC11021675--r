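# Numeric substrate of a sea stack plot: per-group summary statistics,
# bin-width selection on the pooled sample, anchored bin edges shared by
# all groups, and half-open histogram counting.

#' Create a labelled data group
#'
#' A data group is one labelled vector of continuous measurements, the unit
#' from which a sea stack plot is built. Missing values are dropped with a
#' message; non-finite values are an error.
#'
#' @param label Single character label for the group.
#' @param values Numeric vector of measurements; `NA`s are removed.
#' @return An object of class `data_group` with fields `label`, `values`
#'   (finite, no missing) and `n`.
#' @examples
#' g <- data_group("control", c(9.1, 10.2, NA, 11.3))
#' g$n
#' @export
data_group <- function(label, values) {
  stopifnot(is.character(label), length(label) == 1L, nchar(label) > 0L)
  values <- as.numeric(values)
  n_missing <- sum(is.na(values))
  if (n_missing > 0L) {
    message(sprintf("data_group '%s': dropped %d missing value(s)",
                    label, n_missing))
    values <- values[!is.na(values)]
  }
  if (length(values) == 0L) {
    stop(sprintf("group '%s' has no values left after removing missing entries; cannot be plotted",
                 label), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop(sprintf("group '%s' contains non-finite values", label), call. = FALSE)
  }
  structure(list(label = label, values = values, n = length(values)),
            class = "data_group")
}

#' @export
print.data_group <- function(x, ...) {
  cat(sprintf("<data_group '%s': n = %d, range [%g, %g]>\n",
              x$label, x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Summary statistics for one group of measurements
#'
#' Computes the statistics a sea stack plot overlays on the histogram:
#' the mean with its standard deviation (sample SD, divisor n - 1) for the
#' parametric overlay, and the median with the first and third quartiles for
#' the non-parametric one. Quartiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7), stated explicitly because the
#' interquartile range feeds the Freedman-Diaconis bin width.
#'
#' @param values Numeric vector; `NA`s are dropped first.
#' @return An object of class `summary_stats`: list with `mean`, `sd`,
#'   `median`, `q1`, `q3`, `n`.
#' @examples
#' summarise_values(c(0, 10, 20))
#' @export
summarise_values <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("no finite values to summarise; group cannot be plotted", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  n <- length(values)
  if (n == 1L) {
    warning("group of size 1: standard deviation reported as 0", call. = FALSE)
    s <- 0
  } else {
    s <- stats::sd(values)
  }
  q <- unname(stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  structure(list(mean = mean(values), sd = s,
                 median = q[2], q1 = q[1], q3 = q[3], n = n),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats: n = %d, mean = %g, sd = %g, median = %g, IQR [%g, %g]>\n",
              x$n, x$mean, x$sd, x$median, x$q1, x$q3))
  invisible(x)
}

#' Bin-width selection rule
#'
#' @param kind One of `"fixed"`, `"freedman_diaconis"`, `"scott"`,
#'   `"sturges"`.
#' @param width Positive bin width in data units; required iff
#'   `kind = "fixed"`.
#' @return An object of class `bin_rule`.
#' @export
bin_rule <- function(kind = c("freedman_diaconis", "scott", "sturges", "fixed"),
                     width = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(width) || !is.numeric(width) || length(width) != 1L ||
        !is.finite(width) || width <= 0) {
      stop("fixed bin rule requires a single positive width", call. = FALSE)
    }
  } else if (!is.null(width)) {
    stop("width may only be given with kind = 'fixed'", call. = FALSE)
  }
  structure(list(kind = kind, width = width), class = "bin_rule")
}

#' Select a bin width for the pooled sample
#'
#' The bins of a sea stack plot are shared across all groups, so the width
#' is chosen from the pooled values of every group. Supported data-driven
#' rules: Freedman-Diaconis `2 * IQR * n^(-1/3)` (default elsewhere in the
#' package: robust to skew and outliers), Scott `3.49 * sd * n^(-1/3)`, and
#' Sturges `range / (1 + log2(n))`. When a rule degenerates to a zero width
#' the fallback chain is: IQR = 0 -> Scott; sd = 0 (or zero range) -> a
#' single unit-width bin, signalled here by returning width 1.
#'
#' @param pooled_values Numeric vector pooling the values of all groups.
#' @param rule A [bin_rule()].
#' @return A single positive bin width in data units.
#' @examples
#' select_bin_width(1:100, bin_rule("freedman_diaconis"))
#' @export
select_bin_width <- function(pooled_values, rule = bin_rule()) {
  stopifnot(inherits(rule, "bin_rule"))
  values <- as.numeric(pooled_values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to select a bin width from", call. = FALSE)
  if (rule$kind == "fixed") return(rule$width)

  n <- length(values)
  width <- switch(rule$kind,
    freedman_diaconis = {
      iqr <- unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7)))
      2 * iqr * n^(-1 / 3)
    },
    scott = 3.49 * stats::sd(values) * n^(-1 / 3),
    sturges = diff(range(values)) / (1 + log2(n))
  )
  if (is.na(width)) width <- 0 # sd of a single value is NA
  if (width > 0) return(width)

  # Degenerate rule: IQR = 0 falls back to Scott; a zero spread (sd = 0 or
  # zero range) falls back to a single unit-width bin.
  if (rule$kind == "freedman_diaconis") {
    scott_width <- 3.49 * stats::sd(values) * n^(-1 / 3)
    if (!is.na(scott_width) && scott_width > 0) return(scott_width)
  }
  1
}

#' Build shared bin edges anchored at multiples of the width
#'
#' Edges are anchored at integer multiples of the bin width so that bin
#' boundaries fall on round, meaningful values (e.g. whole centimetres in a
#' length-frequency histogram): the first edge is
#' `width * floor(global_min / width)` and the last is the smallest anchored
#' multiple that is `>= global_max`. As a special case, a degenerate span
#' (`global_min == global_max`) yields a single bin of the given width
#' centred on the common value.
#'
#' @param global_min,global_max Pooled minimum and maximum over all groups.
#' @param width Positive bin width.
#' @return Numeric vector of strictly increasing, equally spaced edges.
#' @examples
#' make_edges(0.3, 2.2, 1) # 0 1 2 3
#' @export
make_edges <- function(global_min, global_max, width) {
  stopifnot(is.numeric(global_min), is.numeric(global_max), is.numeric(width),
            length(global_min) == 1L, length(global_max) == 1L,
            length(width) == 1L, is.finite(global_min), is.finite(global_max),
            is.finite(width))
  if (width <= 0) stop("bin width must be positive", call. = FALSE)
  if (global_min > global_max) stop("global_min must be <= global_max", call. = FALSE)
  if (global_min == global_max) {
    return(c(global_min - width / 2, global_min + width / 2))
  }
  first <- width * floor(global_min / width)
  k <- ceiling((global_max - first) / width)
  if (k < 1L) k <- 1L
  # guard against floating-point shortfall of ceiling()
  if (first + k * width < global_max) k <- k + 1L
  first + width * (0:k)
}

#' Count values into bins
#'
#' Interval convention: every bin is half-open `[lo, hi)` except the last,
#' which is closed `[lo, hi]`, so the pooled maximum is counted exactly
#' once. Values outside the edge span are an error (edges must be built
#' from the pooled minimum and maximum).
#'
#' @param values Numeric vector, all within `[edges[1], edges[length(edges)]]`.
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return Integer vector of length `length(edges) - 1` summing to
#'   `length(values)`.
#' @examples
#' bin_counts(c(0, 0, 0, 5), edges = 0:6)
#' @export
bin_counts <- function(values, edges) {
  values <- as.numeric(values)
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  if (length(values) == 0L) return(integer(length(edges) - 1L))
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(values < edges[1]) || any(values > edges[length(edges)])) {
    stop("values outside the bin-edge span; edges must cover the pooled range",
         call. = FALSE)
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Advisory check on group sample size
#'
#' Sea stack plots are recommended for continuous data with sample size
#' n >= 20; below that a raw-data display (e.g. a univariate scatter plot
#' with a boxplot) is more transparent. The check raises a warning but
#' never blocks plotting.
#'
#' @param n Group sample size (positive integer).
#' @param label Optional group label used in the warning message.
#' @return `TRUE` (invisibly) iff the advisory was raised, i.e. n < 20.
#' @export
check_sample_size <- function(n, label = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  flag <- n < 20
  if (flag) {
    who <- if (is.null(label)) "" else sprintf(" in group '%s'", label)
    warning(sprintf(paste0(
      "sample size n = %d%s is below the recommended minimum of 20 for a ",
      "sea stack plot; consider showing the raw data instead"), n, who),
      call. = FALSE)
  }
  invisible(flag)
}

#' Build a histogram with bins shared across groups
#'
#' Pools all groups to choose one bin width and one anchored edge set, then
#' counts each group into those shared bins, so that bin-by-bin comparison
#' across groups is meaningful.
#'
#' @param groups List of [data_group()] objects.
#' @param rule A [bin_rule()]; default Freedman-Diaconis.
#' @return An object of class `stack_histogram`: list with `edges` and
#'   `counts` (named list, one integer vector per group label).
#' @examples
#' g <- list(data_group("a", c(1, 2, 2.5)), data_group("b", c(3, 4)))
#' build_histogram(g, bin_rule("fixed", width = 1))
#' @export
build_histogram <- function(groups, rule = bin_rule()) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "data_group")))
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate group labels", call. = FALSE)
  pooled <- unlist(lapply(groups, `[[`, "values"), use.names = FALSE)
  width <- select_bin_width(pooled, rule)
  edges <- make_edges(min(pooled), max(pooled), width)
  counts <- lapply(groups, function(g) bin_counts(g$values, edges))
  names(counts) <- labels
  structure(list(edges = edges, counts = counts), class = "stack_histogram")
}

#' @export
print.stack_histogram <- function(x, ...) {
  cat(sprintf("<stack_histogram: %d bins of width %g over [%g, %g], %d group(s)>\n",
              length(x$edges) - 1L, x$edges[2] - x$edges[1],
              x$edges[1], x$edges[length(x$edges)], length(x$counts)))
  invisible(x)
}
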