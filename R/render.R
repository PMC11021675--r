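# Rendering: turn resolved stack geometry into figure files.
#
# SVG output is written directly as text so that identical inputs give
# byte-identical files (a property the tests assert); numbers are formatted
# with a fixed precision and no locale dependence. PNG and PDF go through
# the standard graphics devices and are not guaranteed byte-stable across
# platforms.

#' Rendering specification
#'
#' @param path Output file path; the format is inferred from the extension
#'   (`.svg`, `.png`, `.pdf`) unless `format` is given.
#' @param format One of `"svg"`, `"png"`, `"pdf"`, or `NULL` to infer.
#' @param width_in,height_in Figure size in inches.
#' @param dpi Resolution for PNG output.
#' @param value_lab,group_lab Axis labels (value axis, group axis).
#' @param show_count_ticks Draw per-slot count ticks at 0 and at the
#'   maximum count (default `TRUE`); the full tick grid is intentionally
#'   omitted to avoid clutter.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(path, format = NULL, width_in = 7, height_in = 5,
                        dpi = 96, value_lab = "value", group_lab = "group",
                        show_count_ticks = TRUE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("svg", "png", "pdf")) {
      stop("cannot infer format from extension '", ext,
           "'; use format = 'svg', 'png' or 'pdf'", call. = FALSE)
    }
    format <- ext
  }
  if (!format %in% c("svg", "png", "pdf")) {
    stop("unsupported format: ", format, call. = FALSE)
  }
  stopifnot(width_in > 0, height_in > 0, dpi > 0)
  structure(list(path = path, format = format, width_in = width_in,
                 height_in = height_in, dpi = dpi, value_lab = value_lab,
                 group_lab = group_lab,
                 show_count_ticks = isTRUE(show_count_ticks)),
            class = "render_spec")
}

#' Legend caption for a sea stack plot
#'
#' Count bars share one scale whose maximum is not printed on the axis;
#' instead the caption reports it, together with the meaning of the summary
#' glyphs for the style in use.
#'
#' @param geometry A `stack_geometry` (or anything with a `max_count`
#'   field).
#' @param summary_style `"parametric"`, `"nonparametric"`, `"both"` or
#'   `"none"`; defaults to the geometry's own style.
#' @return A single caption string.
#' @examples
#' g <- figure1_groups(seed = 1)
#' geo <- build_stack(g, build_histogram(g, bin_rule("fixed", 1)))
#' legend_text(geo)
#' @export
legend_text <- function(geometry, summary_style = NULL) {
  stopifnot(!is.null(geometry$max_count))
  if (is.null(summary_style)) {
    summary_style <- if (is.null(geometry$summary_style)) "parametric"
                     else geometry$summary_style
  }
  summary_style <- match.arg(summary_style,
                             c("parametric", "nonparametric", "both", "none"))
  scale_part <- sprintf(
    "Bar lengths show bin counts from 0 (baseline) to a maximum of %d.",
    as.integer(geometry$max_count))
  para <- paste("The white diamond marks the group mean and the dark grey",
                "bar spans mean ± 1 SD.")
  nonpara <- paste("The filled circle marks the group median and the thin",
                   "bar spans the quartile range (q1–q3).")
  glyph_part <- switch(summary_style,
    parametric = para,
    nonparametric = nonpara,
    both = paste(para, nonpara),
    none = NULL)
  paste(c(scale_part, glyph_part), collapse = " ")
}

fmt_num <- function(x) {
  # fixed-precision, locale-independent number formatting for SVG output
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

svg_tag <- function(name, ..., children = NULL) {
  attrs <- c(...)
  attr_str <- if (length(attrs) > 0L) {
    paste0(" ", paste0(names(attrs), "=\"", attrs, "\"", collapse = " "))
  } else ""
  if (is.null(children)) {
    paste0("<", name, attr_str, "/>")
  } else {
    paste0("<", name, attr_str, ">", paste0(children, collapse = ""),
           "</", name, ">")
  }
}

# Map data coordinates to SVG pixel coordinates (SVG y grows downwards).
make_mapper <- function(xlim, ylim, width_px, height_px, margin) {
  plot_w <- width_px - margin$left - margin$right
  plot_h <- height_px - margin$top - margin$bottom
  list(
    x = function(x) margin$left + (x - xlim[1]) / diff(xlim) * plot_w,
    y = function(y) height_px - margin$bottom -
      (y - ylim[1]) / diff(ylim) * plot_h
  )
}

build_svg <- function(geometry, spec) {
  rects <- stack_rects(geometry)
  width_px <- spec$width_in * 96
  height_px <- spec$height_in * 96
  margin <- list(left = 56, right = 16, top = 16, bottom = 44)

  vertical <- geometry$orientation == "vertical"
  G <- length(geometry$slots)
  value_rng <- range(geometry$edges)
  # include summary glyph extents (mean +/- SD may exceed the data range)
  for (s in geometry$slots) {
    if (geometry$summary_style %in% c("parametric", "both")) {
      value_rng <- range(value_rng, s$sd_bar$value_lo, s$sd_bar$value_hi)
    }
    if (geometry$summary_style %in% c("nonparametric", "both")) {
      value_rng <- range(value_rng, s$quartile_bar$value_lo,
                         s$quartile_bar$value_hi)
    }
  }
  value_pad <- 0.04 * diff(value_rng)
  if (value_pad == 0) value_pad <- 0.5
  value_lim <- value_rng + c(-value_pad, value_pad)
  group_lim <- c(1 - geometry$slot_width, G + geometry$slot_width)

  if (vertical) {
    xlim <- group_lim; ylim <- value_lim
    xlab <- spec$group_lab; ylab <- spec$value_lab
  } else {
    xlim <- value_lim; ylim <- group_lim
    xlab <- spec$value_lab; ylab <- spec$group_lab
  }
  m <- make_mapper(xlim, ylim, width_px, height_px, margin)

  body <- character(0)
  add <- function(...) body <<- c(body, ...)

  # bar rectangles (one per non-empty bin)
  for (i in seq_len(nrow(rects))) {
    x0 <- m$x(min(rects$x0[i], rects$x1[i]))
    x1 <- m$x(max(rects$x0[i], rects$x1[i]))
    y0 <- m$y(max(rects$y0[i], rects$y1[i]))  # SVG y is flipped
    y1 <- m$y(min(rects$y0[i], rects$y1[i]))
    add(svg_tag("rect",
      x = fmt_num(x0), y = fmt_num(y0),
      width = fmt_num(x1 - x0), height = fmt_num(y1 - y0),
      fill = geometry$bar_fill, `fill-opacity` = fmt_num(geometry$bar_alpha),
      stroke = "#FFFFFF", `stroke-width` = "0.5",
      class = "stack-bar"))
  }

  pt <- function(value, at) {
    # (value-axis coord, group-axis coord) -> pixel (x, y)
    if (vertical) c(m$x(at), m$y(value)) else c(m$x(value), m$y(at))
  }

  for (s in geometry$slots) {
    base <- s$baseline
    if (geometry$summary_style %in% c("parametric", "both")) {
      p0 <- pt(s$sd_bar$value_lo, base); p1 <- pt(s$sd_bar$value_hi, base)
      add(svg_tag("line", x1 = fmt_num(p0[1]), y1 = fmt_num(p0[2]),
                  x2 = fmt_num(p1[1]), y2 = fmt_num(p1[2]),
                  stroke = "#4D4D4D", `stroke-width` = "3",
                  class = "sd-bar"))
      c0 <- pt(s$mean_glyph$value, base)
      r <- 4.5
      pts <- sprintf("%s,%s %s,%s %s,%s %s,%s",
                     fmt_num(c0[1]), fmt_num(c0[2] - r),
                     fmt_num(c0[1] + r), fmt_num(c0[2]),
                     fmt_num(c0[1]), fmt_num(c0[2] + r),
                     fmt_num(c0[1] - r), fmt_num(c0[2]))
      add(svg_tag("polygon", points = pts, fill = "#FFFFFF",
                  stroke = "#000000", `stroke-width` = "1",
                  class = "mean-diamond"))
    }
    if (geometry$summary_style %in% c("nonparametric", "both")) {
      p0 <- pt(s$quartile_bar$value_lo, base)
      p1 <- pt(s$quartile_bar$value_hi, base)
      add(svg_tag("line", x1 = fmt_num(p0[1]), y1 = fmt_num(p0[2]),
                  x2 = fmt_num(p1[1]), y2 = fmt_num(p1[2]),
                  stroke = "#000000", `stroke-width` = "1.2",
                  class = "quartile-bar"))
      c0 <- pt(s$median_glyph$value, base)
      add(svg_tag("circle", cx = fmt_num(c0[1]), cy = fmt_num(c0[2]),
                  r = "3", fill = "#000000", class = "median-dot"))
    }
    # per-slot count ticks: 0 at the baseline, max_count at full extension
    if (spec$show_count_ticks) {
      scale_max <- if (geometry$count_scaling == "global") geometry$max_count
                   else max(c(0, s$bars$count))
      for (tick in list(c(base, "0"),
                        c(base - geometry$slot_width,
                          as.character(scale_max)))) {
        at <- as.numeric(tick[[1]])
        p0 <- if (vertical) c(m$x(at), height_px - margin$bottom)
              else c(margin$left, m$y(at))
        tick_len <- 4
        if (vertical) {
          add(svg_tag("line", x1 = fmt_num(p0[1]), y1 = fmt_num(p0[2]),
                      x2 = fmt_num(p0[1]), y2 = fmt_num(p0[2] + tick_len),
                      stroke = "#000000", `stroke-width` = "1",
                      class = "count-tick"))
          add(svg_tag("text", x = fmt_num(p0[1]),
                      y = fmt_num(p0[2] + tick_len + 10),
                      `text-anchor` = "middle", `font-size` = "9",
                      `font-family` = "sans-serif",
                      children = tick[[2]]))
        } else {
          add(svg_tag("line", x1 = fmt_num(p0[1] - tick_len),
                      y1 = fmt_num(p0[2]),
                      x2 = fmt_num(p0[1]), y2 = fmt_num(p0[2]),
                      stroke = "#000000", `stroke-width` = "1",
                      class = "count-tick"))
          add(svg_tag("text", x = fmt_num(p0[1] - tick_len - 3),
                      y = fmt_num(p0[2] + 3),
                      `text-anchor` = "end", `font-size` = "9",
                      `font-family` = "sans-serif",
                      children = tick[[2]]))
        }
      }
    }
  }

  # value axis (left side when vertical) with pretty ticks
  vticks <- pretty(value_lim, n = 6)
  vticks <- vticks[vticks >= value_lim[1] & vticks <= value_lim[2]]
  if (vertical) {
    add(svg_tag("line", x1 = fmt_num(margin$left), y1 = fmt_num(margin$top),
                x2 = fmt_num(margin$left),
                y2 = fmt_num(height_px - margin$bottom),
                stroke = "#000000", `stroke-width` = "1", class = "axis"))
    for (v in vticks) {
      yv <- m$y(v)
      add(svg_tag("line", x1 = fmt_num(margin$left - 4), y1 = fmt_num(yv),
                  x2 = fmt_num(margin$left), y2 = fmt_num(yv),
                  stroke = "#000000", `stroke-width` = "1"))
      add(svg_tag("text", x = fmt_num(margin$left - 7), y = fmt_num(yv + 3),
                  `text-anchor` = "end", `font-size` = "10",
                  `font-family` = "sans-serif", children = fmt_num(v)))
    }
  } else {
    add(svg_tag("line", x1 = fmt_num(margin$left),
                y1 = fmt_num(height_px - margin$bottom),
                x2 = fmt_num(width_px - margin$right),
                y2 = fmt_num(height_px - margin$bottom),
                stroke = "#000000", `stroke-width` = "1", class = "axis"))
    for (v in vticks) {
      xv <- m$x(v)
      y0 <- height_px - margin$bottom
      add(svg_tag("line", x1 = fmt_num(xv), y1 = fmt_num(y0),
                  x2 = fmt_num(xv), y2 = fmt_num(y0 + 4),
                  stroke = "#000000", `stroke-width` = "1"))
      add(svg_tag("text", x = fmt_num(xv), y = fmt_num(y0 + 15),
                  `text-anchor` = "middle", `font-size` = "10",
                  `font-family` = "sans-serif", children = fmt_num(v)))
    }
  }

  # group labels at slot centres
  for (s in geometry$slots) {
    if (vertical) {
      add(svg_tag("text", x = fmt_num(m$x(s$slot_center)),
                  y = fmt_num(height_px - margin$bottom + 28),
                  `text-anchor` = "middle", `font-size` = "11",
                  `font-family` = "sans-serif", children = s$label))
    } else {
      add(svg_tag("text", x = fmt_num(margin$left - 7),
                  y = fmt_num(m$y(s$slot_center) + 3),
                  `text-anchor` = "end", `font-size` = "11",
                  `font-family` = "sans-serif", children = s$label))
    }
  }

  # axis titles
  add(svg_tag("text", x = fmt_num(width_px / 2),
              y = fmt_num(height_px - 6), `text-anchor` = "middle",
              `font-size` = "12", `font-family` = "sans-serif",
              children = xlab))
  add(svg_tag("text", x = "12", y = fmt_num(height_px / 2),
              transform = sprintf("rotate(-90 12 %s)", fmt_num(height_px / 2)),
              `text-anchor` = "middle", `font-size` = "12",
              `font-family` = "sans-serif", children = ylab))

  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">\n"),
            fmt_num(width_px), fmt_num(height_px),
            fmt_num(width_px), fmt_num(height_px)),
    "<rect width=\"100%\" height=\"100%\" fill=\"#FFFFFF\"/>\n",
    paste0(body, collapse = "\n"), "\n</svg>\n")
}

draw_base_graphics <- function(geometry, spec) {
  rects <- stack_rects(geometry)
  vertical <- geometry$orientation == "vertical"
  G <- length(geometry$slots)
  value_rng <- range(geometry$edges)
  for (s in geometry$slots) {
    if (geometry$summary_style %in% c("parametric", "both")) {
      value_rng <- range(value_rng, s$sd_bar$value_lo, s$sd_bar$value_hi)
    }
  }
  group_lim <- c(1 - geometry$slot_width, G + geometry$slot_width)
  if (vertical) {
    xlim <- group_lim; ylim <- value_rng
    xlab <- spec$group_lab; ylab <- spec$value_lab
  } else {
    xlim <- value_rng; ylim <- group_lim
    xlab <- spec$value_lab; ylab <- spec$group_lab
  }
  graphics::plot.new()
  graphics::plot.window(xlim = xlim, ylim = ylim)
  graphics::rect(rects$x0, rects$y0, rects$x1, rects$y1,
                 col = grDevices::adjustcolor(geometry$bar_fill,
                                              alpha.f = geometry$bar_alpha),
                 border = "white", lwd = 0.5)
  for (s in geometry$slots) {
    b <- s$baseline
    if (geometry$summary_style %in% c("parametric", "both")) {
      if (vertical) {
        graphics::segments(b, s$sd_bar$value_lo, b, s$sd_bar$value_hi,
                           col = "grey30", lwd = 3)
        graphics::points(b, s$mean_glyph$value, pch = 23, bg = "white",
                         cex = 1.2)
      } else {
        graphics::segments(s$sd_bar$value_lo, b, s$sd_bar$value_hi, b,
                           col = "grey30", lwd = 3)
        graphics::points(s$mean_glyph$value, b, pch = 23, bg = "white",
                         cex = 1.2)
      }
    }
    if (geometry$summary_style %in% c("nonparametric", "both")) {
      if (vertical) {
        graphics::segments(b, s$quartile_bar$value_lo, b,
                           s$quartile_bar$value_hi, lwd = 1.2)
        graphics::points(b, s$median_glyph$value, pch = 16, cex = 0.9)
      } else {
        graphics::segments(s$quartile_bar$value_lo, b,
                           s$quartile_bar$value_hi, b, lwd = 1.2)
        graphics::points(s$median_glyph$value, b, pch = 16, cex = 0.9)
      }
    }
  }
  centres <- vapply(geometry$slots, `[[`, numeric(1), "slot_center")
  labels <- vapply(geometry$slots, `[[`, character(1), "label")
  if (vertical) {
    graphics::axis(2)
    graphics::axis(1, at = centres, labels = labels, tick = FALSE)
  } else {
    graphics::axis(1)
    graphics::axis(2, at = centres, labels = labels, tick = FALSE, las = 1)
  }
  graphics::title(xlab = xlab, ylab = ylab)
  graphics::box(bty = "l")
}

#' Render a sea stack plot to a file
#'
#' SVG output is generated as text and is byte-identical for identical
#' inputs; PNG and PDF go through the standard graphics devices.
#'
#' @param geometry A [build_stack()] result (possibly re-oriented with
#'   [orient()]).
#' @param spec A [render_spec()].
#' @return The output path, invisibly.
#' @examples
#' g <- figure1_groups(seed = 1)
#' geo <- build_stack(g, build_histogram(g, bin_rule("fixed", 1)))
#' out <- file.path(tempdir(), "stack.svg")
#' render_figure(geo, render_spec(out))
#' @export
render_figure <- function(geometry, spec) {
  stopifnot(inherits(spec, "render_spec"))
  if (!inherits(geometry, "stack_geometry") ||
      length(geometry$slots) == 0L) {
    stop("empty or invalid geometry: nothing to render", call. = FALSE)
  }
  dir <- dirname(spec$path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  switch(spec$format,
    svg = {
      con <- file(spec$path, open = "wb")
      on.exit(close(con))
      writeBin(charToRaw(build_svg(geometry, spec)), con)
    },
    png = {
      grDevices::png(spec$path, width = spec$width_in, height = spec$height_in,
                     units = "in", res = spec$dpi)
      on.exit(grDevices::dev.off())
      draw_base_graphics(geometry, spec)
    },
    pdf = {
      grDevices::pdf(spec$path, width = spec$width_in,
                     height = spec$height_in)
      on.exit(grDevices::dev.off())
      draw_base_graphics(geometry, spec)
    })
  invisible(spec$path)
}

#' One-call sea stack plot
#'
#' Convenience wrapper: groups in, figure file out. Computes shared-bin
#' histograms, per-group summaries (raising the n < 20 advisory per group),
#' builds the geometry and renders it.
#'
#' @param groups List of [data_group()] objects.
#' @param path Output figure path (`.svg`, `.png` or `.pdf`).
#' @param rule A [bin_rule()].
#' @param config A [plot_config()].
#' @param spec Optional [render_spec()]; built from `path` when `NULL`.
#' @return The `stack_geometry`, invisibly.
#' @export
sea_stack_plot <- function(groups, path, rule = bin_rule(),
                           config = plot_config(), spec = NULL) {
  for (g in groups) check_sample_size(g$n, g$label)
  hist <- build_histogram(groups, rule)
  geo <- build_stack(groups, hist, config = config)
  geo <- orient(geo, config$orientation)
  if (is.null(spec)) spec <- render_spec(path)
  render_figure(geo, spec)
  invisible(geo)
}
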