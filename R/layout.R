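# Layout: resolve histograms + summaries into drawing geometry.
#
# Coordinate model: every primitive carries an interval on the value axis
# (v0, v1) and an interval on the group axis (g0, g1). In the vertical
# orientation the value axis is drawn as y and the group axis as x; group
# slots sit at integer positions 1..G, each bar extends LEFT (towards
# smaller group-axis coordinates) from the slot baseline at
# slot_center + slot_width / 2. Orientation is resolved by orient(), which
# simply exchanges the two coordinate pairs.

#' Plot configuration for a sea stack plot
#'
#' @param orientation `"vertical"` (value axis vertical, the default) or
#'   `"horizontal"`.
#' @param summary_style Which summary overlay to draw: `"parametric"`
#'   (white diamond at the mean, dark grey bar spanning mean +/- 1 SD),
#'   `"nonparametric"` (filled circle at the median, thin bar spanning
#'   q1-q3), `"both"`, or `"none"`.
#' @param slot_width Maximum bar length on the group axis, in group-axis
#'   units; must lie in (0, 1] so neighbouring slots cannot overlap.
#' @param count_scaling `"global"` (one count-to-length scale shared by all
#'   groups, enabling cross-group size comparison; the default) or
#'   `"per_group"` (each group's own maximum count fills the slot).
#' @param bar_fill,bar_alpha Render hints for bar colour and opacity.
#' @return An object of class `plot_config`.
#' @export
plot_config <- function(orientation = c("vertical", "horizontal"),
                        summary_style = c("parametric", "nonparametric",
                                          "both", "none"),
                        slot_width = 0.8,
                        count_scaling = c("global", "per_group"),
                        bar_fill = "#4878A8", bar_alpha = 1) {
  orientation <- match.arg(orientation)
  summary_style <- match.arg(summary_style)
  count_scaling <- match.arg(count_scaling)
  stopifnot(is.numeric(slot_width), length(slot_width) == 1L,
            slot_width > 0, slot_width <= 1,
            is.numeric(bar_alpha), bar_alpha >= 0, bar_alpha <= 1)
  structure(list(orientation = orientation, summary_style = summary_style,
                 slot_width = slot_width, count_scaling = count_scaling,
                 bar_fill = bar_fill, bar_alpha = bar_alpha),
            class = "plot_config")
}

#' Scale bin counts to bar lengths
#'
#' Bar length is exactly proportional to the bin count:
#' `slot_width * count / max_count`, so the bin holding `max_count` values
#' fills the slot exactly and ratios of lengths equal ratios of counts.
#'
#' @param counts Non-negative integer vector of bin counts.
#' @param max_count Positive scaling maximum, `>= max(counts)`.
#' @param slot_width Maximum bar length (group-axis units).
#' @return Numeric vector of bar lengths in `[0, slot_width]`.
#' @export
scale_bar_lengths <- function(counts, max_count, slot_width) {
  stopifnot(is.numeric(counts), all(counts >= 0),
            is.numeric(max_count), length(max_count) == 1L,
            is.numeric(slot_width), length(slot_width) == 1L, slot_width > 0)
  if (max_count == 0) stop("max_count is 0: no data to scale", call. = FALSE)
  if (max(counts) > max_count) {
    stop("max_count must be >= max(counts)", call. = FALSE)
  }
  # counts / max_count first so a full bin maps to slot_width exactly
  slot_width * (counts / max_count)
}

#' Build the drawing geometry of a sea stack plot
#'
#' Places group slots at integer positions 1..G on the group axis. Within
#' each slot, non-empty bins become rectangles extending left from the slot
#' baseline (the slot's right edge at `slot_center + slot_width / 2`), with
#' length proportional to the bin count. Summary glyphs are placed on the
#' baseline so they never occlude the bars: a white diamond at the mean with
#' a dark grey bar spanning mean +/- 1 SD (parametric), and/or a filled
#' circle at the median with a thin bar spanning q1-q3 (non-parametric).
#' The summary bar is deliberately not clipped to the observed data range:
#' it draws the statistic, not the data, so mean - SD may extend below the
#' smallest observation (e.g. below 0 for zero-inflated data).
#'
#' @param groups List of [data_group()] objects.
#' @param histogram A [build_histogram()] result covering all groups.
#' @param stats Named list of [summarise_values()] results, one per group
#'   label (computed from the groups when `NULL`).
#' @param config A [plot_config()].
#' @return An object of class `stack_geometry`: per-group slot centres,
#'   baselines, bar rectangles and glyph positions, plus the global
#'   `max_count` used for length scaling (reported in the legend).
#' @examples
#' g <- figure1_groups(seed = 1)
#' geo <- build_stack(g, build_histogram(g, bin_rule("fixed", width = 1)))
#' geo$max_count
#' @export
build_stack <- function(groups, histogram, stats = NULL,
                        config = plot_config()) {
  stopifnot(inherits(histogram, "stack_histogram"),
            inherits(config, "plot_config"),
            is.list(groups), length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "data_group")))
  labels <- vapply(groups, `[[`, character(1), "label")
  missing_counts <- setdiff(labels, names(histogram$counts))
  if (length(missing_counts) > 0L) {
    stop("histogram does not cover group(s): ",
         paste(missing_counts, collapse = ", "), call. = FALSE)
  }
  if (is.null(stats)) {
    stats <- lapply(groups, function(g) summarise_values(g$values))
    names(stats) <- labels
  }
  missing_stats <- setdiff(labels, names(stats))
  if (length(missing_stats) > 0L) {
    stop("unknown group label(s) in stats: ",
         paste(missing_stats, collapse = ", "), call. = FALSE)
  }

  edges <- histogram$edges
  nbin <- length(edges) - 1L
  max_count_global <- max(vapply(histogram$counts[labels], max, numeric(1)))
  if (max_count_global == 0) stop("all bins empty: nothing to draw", call. = FALSE)

  slots <- lapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    counts <- histogram$counts[[lab]]
    scale_max <- if (config$count_scaling == "global") max_count_global
                 else max(counts)
    lengths <- scale_bar_lengths(counts, scale_max, config$slot_width)
    center <- i
    baseline <- center + config$slot_width / 2
    keep <- counts > 0L
    bars <- data.frame(
      value_lo = edges[seq_len(nbin)][keep],
      value_hi = edges[-1L][keep],
      count = counts[keep],
      length = lengths[keep],
      g0 = baseline - lengths[keep],
      g1 = baseline
    )
    st <- stats[[lab]]
    list(label = lab, slot_center = center, baseline = baseline,
         bars = bars,
         mean_glyph = list(value = st$mean, at = baseline,
                           style = "diamond", fill = "white"),
         sd_bar = list(value_lo = st$mean - st$sd,
                       value_hi = st$mean + st$sd,
                       at = baseline, style = "dark_grey_bar"),
         median_glyph = list(value = st$median, at = baseline,
                             style = "circle", fill = "black"),
         quartile_bar = list(value_lo = st$q1, value_hi = st$q3,
                             at = baseline, style = "thin_bar"))
  })
  names(slots) <- labels

  structure(list(slots = slots, edges = edges,
                 max_count = max_count_global,
                 orientation = "vertical",
                 summary_style = config$summary_style,
                 slot_width = config$slot_width,
                 count_scaling = config$count_scaling,
                 bar_fill = config$bar_fill, bar_alpha = config$bar_alpha),
            class = "stack_geometry")
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("<stack_geometry: %d group slot(s), %d bin(s), max count %d, %s>\n",
              length(x$slots), length(x$edges) - 1L, x$max_count,
              x$orientation))
  invisible(x)
}

#' Re-orient stack geometry
#'
#' `"vertical"` is the identity. `"horizontal"` exchanges the value-axis
#' and group-axis coordinates of every primitive, so applying it twice
#' returns the original geometry (an involution). The vertical layout is
#' the canonical one: flipped a quarter turn to the right its value axis
#' reads left (small) to right (large) along the top.
#'
#' @param geometry A [build_stack()] result.
#' @param orientation `"vertical"` or `"horizontal"`.
#' @return The re-oriented `stack_geometry`.
#' @export
orient <- function(geometry, orientation = c("vertical", "horizontal")) {
  stopifnot(inherits(geometry, "stack_geometry"))
  orientation <- match.arg(orientation)
  if (orientation == "vertical") return(geometry)
  geometry$orientation <- if (geometry$orientation == "vertical")
    "horizontal" else "vertical"
  geometry
}

#' Bar rectangles of a stack geometry in drawing coordinates
#'
#' Resolves every bar to an (x, y) rectangle honouring the geometry's
#' orientation: vertical puts the value axis on y, horizontal exchanges the
#' axes. Used by the renderer and convenient in tests.
#'
#' @param geometry A `stack_geometry`.
#' @return A data.frame with columns `group`, `x0`, `x1`, `y0`, `y1`,
#'   `count`; one row per non-empty bin.
#' @export
stack_rects <- function(geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  rows <- lapply(geometry$slots, function(s) {
    b <- s$bars
    if (nrow(b) == 0L) return(NULL)
    data.frame(group = s$label, v0 = b$value_lo, v1 = b$value_hi,
               g0 = b$g0, g1 = b$g1, count = b$count)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (geometry$orientation == "vertical") {
    data.frame(group = df$group, x0 = df$g0, x1 = df$g1,
               y0 = df$v0, y1 = df$v1, count = df$count)
  } else {
    data.frame(group = df$group, x0 = df$v0, x1 = df$v1,
               y0 = df$g0, y1 = df$g1, count = df$count)
  }
}
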