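# Palm patterns: schematic bar diagrams of a digenean body.
#
# A worm is drawn as a black bar for total body length, with coloured bars
# marking the longitudinal position and range of each organ. In "absolute"
# mode all bodies are drawn at the same axis length, divided into eighths, so
# organ *positions* are comparable; in "relative" mode bodies are drawn to
# scale and centre-aligned on a shared transverse axis, so *sizes* are
# comparable.

#' Build a Palm pattern from organ extents
#'
#' Normalizes organ extents by body length into bar fractions. Extents must
#' already be valid (use [reconstruct_extents()]; rows with status
#' `"invalid"` are rejected here).
#'
#' @param extents Tibble with columns `organ`, `anterior`, `posterior`
#'   (µm), e.g. from [reconstruct_extents()] (optionally with `status`).
#' @param body_length Body length in µm (> 0).
#' @param taxon Label for the pattern.
#' @param palette Named colour vector; see [organ_palette()].
#' @return An object of class `palm_pattern`: list with `taxon`,
#'   `body_length`, `bars` (tibble `organ`, `start_fraction`, `end_fraction`,
#'   `color`, sorted by start) and `gridlines` (the seven eighth boundaries).
#' @export
palm_pattern <- function(extents, body_length, taxon,
                         palette = organ_palette()) {
  stopifnot(is.numeric(body_length), length(body_length) == 1L,
            body_length > 0)
  if (is.null(extents) || nrow(extents) == 0L) {
    bars <- tibble(organ = character(0), start_fraction = numeric(0),
                   end_fraction = numeric(0), color = character(0))
  } else {
    stopifnot(all(c("organ", "anterior", "posterior") %in% names(extents)))
    if ("status" %in% names(extents)) {
      bad <- extents$status == "invalid"
      if (any(bad)) {
        abort(paste0("Invalid extents must be resolved before plotting: ",
                     paste(extents$organ[bad], collapse = ", ")))
      }
    }
    tol <- 1e-9 * body_length
    if (any(extents$anterior < -tol | extents$posterior > body_length + tol |
              extents$anterior >= extents$posterior)) {
      abort("Extents must satisfy 0 <= anterior < posterior <= body_length.")
    }
    bars <- tibble(
      organ = extents$organ,
      start_fraction = pmax(extents$anterior, 0) / body_length,
      end_fraction = pmin(extents$posterior, body_length) / body_length,
      color = organ_color(extents$organ, palette)
    )
    bars <- arrange(bars, .data$start_fraction, .data$organ)
  }
  structure(
    list(taxon = taxon, body_length = body_length, bars = bars,
         gridlines = seq_len(7) / 8),
    class = "palm_pattern"
  )
}

#' @export
print.palm_pattern <- function(x, ...) {
  cat(sprintf("Palm pattern: %s (body length %.1f um, %d organ bars)\n",
              x$taxon, x$body_length, nrow(x$bars)))
  if (nrow(x$bars) > 0) print(x$bars)
  invisible(x)
}

#' Arrange Palm patterns into a comparison plate
#'
#' @param patterns A list of [palm_pattern()] objects (column order = input
#'   order).
#' @param mode `"absolute"`: all bodies drawn at the same axis length with
#'   eighth gridlines; `"relative"`: drawn lengths proportional to body
#'   length, bodies centre-aligned on a shared transverse axis, with a µm
#'   scale bar.
#' @return An object of class `palm_plate`.
#' @export
palm_plate <- function(patterns, mode = c("absolute", "relative")) {
  mode <- arg_match(mode)
  if (inherits(patterns, "palm_pattern")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1L,
            all(map_lgl(patterns, inherits, "palm_pattern")))
  structure(list(patterns = patterns, mode = mode), class = "palm_plate")
}

#' @export
print.palm_plate <- function(x, ...) {
  cat(sprintf("Palm plate (%s mode): %d taxa\n", x$mode, length(x$patterns)))
  cat(paste0("  ", map_chr(x$patterns, "taxon"), collapse = "\n"), "\n")
  invisible(x)
}

#' Plate geometry and style configuration
#'
#' @param axis_length Drawn axis length (drawing units) of the longest body
#'   (relative mode) or of every body (absolute mode).
#' @param column_gap Horizontal gap between taxon columns.
#' @param body_bar_width Width of the black body bar.
#' @param organ_bar_width Width of each coloured organ bar.
#' @param lane_gap Gap between parallel organ-bar lanes.
#' @param margin Outer margin.
#' @param scale_bar_um Scale-bar length in µm (relative mode).
#' @param font_size Label font size.
#' @param palette Named organ colour vector.
#' @return A list of class `plate_config`.
#' @export
plate_config <- function(axis_length = 400, column_gap = 36,
                         body_bar_width = 14, organ_bar_width = 7,
                         lane_gap = 2, margin = 40, scale_bar_um = 300,
                         font_size = 11, palette = organ_palette()) {
  if (axis_length <= 0) abort("`axis_length` must be positive.")
  structure(list(axis_length = axis_length, column_gap = column_gap,
                 body_bar_width = body_bar_width,
                 organ_bar_width = organ_bar_width, lane_gap = lane_gap,
                 margin = margin, scale_bar_um = scale_bar_um,
                 font_size = font_size, palette = palette),
            class = "plate_config")
}

# Greedy lane assignment so overlapping organ bars sit in parallel
# sub-columns instead of on top of each other. Deterministic: bars are
# pre-sorted by start fraction then organ name.
assign_lanes <- function(bars) {
  if (nrow(bars) == 0L) return(integer(0))
  lane_end <- numeric(0)
  lanes <- integer(nrow(bars))
  for (i in seq_len(nrow(bars))) {
    free <- which(lane_end <= bars$start_fraction[i] + 1e-12)
    if (length(free) == 0L) {
      lane_end <- c(lane_end, bars$end_fraction[i])
      lanes[i] <- length(lane_end)
    } else {
      lanes[i] <- free[1]
      lane_end[free[1]] <- bars$end_fraction[i]
    }
  }
  lanes
}

# Per-column drawing geometry shared by the SVG and ggplot backends.
# Returns a list with per-pattern tibbles of rectangles in drawing units
# (y grows downward from the top margin; anterior at top).
plate_geometry <- function(plate, config = plate_config()) {
  pats <- plate$patterns
  n <- length(pats)
  max_lanes <- max(1L, map_int(pats, function(p) {
    b <- p$bars
    if (nrow(b) == 0L) 0L else max(assign_lanes(b))
  }))
  col_width <- config$body_bar_width + config$lane_gap +
    max_lanes * (config$organ_bar_width + config$lane_gap)
  Ls <- map_dbl(pats, "body_length")
  upm <- config$axis_length / max(Ls)   # drawing units per µm (relative mode)
  cols <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pats[[i]]
    x0 <- config$margin + (i - 1) * (col_width + config$column_gap)
    if (plate$mode == "absolute") {
      h <- config$axis_length
      y0 <- config$margin
    } else {
      h <- p$body_length * upm
      y0 <- config$margin + (config$axis_length - h) / 2  # midpoints aligned
    }
    bars <- p$bars
    lanes <- assign_lanes(bars)
    organ_x <- x0 + config$body_bar_width + config$lane_gap +
      (lanes - 1) * (config$organ_bar_width + config$lane_gap)
    cols[[i]] <- list(
      taxon = p$taxon, x0 = x0, y0 = y0, height = h,
      body = tibble(x = x0, y = y0, w = config$body_bar_width, h = h),
      organs = tibble(organ = bars$organ, color = bars$color,
                      x = organ_x, w = config$organ_bar_width,
                      y = y0 + bars$start_fraction * h,
                      h = (bars$end_fraction - bars$start_fraction) * h),
      gridlines = if (plate$mode == "absolute")
        tibble(k = seq_len(7), y = y0 + seq_len(7) / 8 * h,
               x1 = x0 - 4, x2 = x0 + col_width) else
          tibble(k = integer(0), y = numeric(0), x1 = numeric(0),
                 x2 = numeric(0))
    )
  }
  canvas_w <- config$margin * 2 + n * col_width + (n - 1) * config$column_gap
  canvas_h <- config$margin * 2 + config$axis_length + 3 * config$font_size
  list(columns = cols, col_width = col_width, units_per_um = upm,
       canvas = c(width = canvas_w, height = canvas_h))
}

fmt_u <- function(x) sprintf("%.3f", x)

svg_rect <- function(x, y, w, h, fill, id, class) {
  sprintf('<rect id="%s" class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
          id, class, fmt_u(x), fmt_u(y), fmt_u(w), fmt_u(h), fill)
}

svg_line <- function(x1, y1, x2, y2, id, class, stroke = "#888888",
                     width = 0.75) {
  sprintf('<line id="%s" class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          id, class, fmt_u(x1), fmt_u(y1), fmt_u(x2), fmt_u(y2), stroke,
          fmt_u(width))
}

svg_text <- function(x, y, label, id, class, size, anchor = "middle") {
  sprintf('<text id="%s" class="%s" x="%s" y="%s" font-size="%s" font-family="Helvetica" text-anchor="%s">%s</text>',
          id, class, fmt_u(x), fmt_u(y), fmt_u(size), anchor,
          xml_escape(label))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a Palm-pattern plate as a deterministic SVG document
#'
#' Produces byte-stable SVG 1.1 text for a fixed plate and configuration: no
#' timestamps, fixed element order and ids, fixed number formatting. Absolute
#' plates carry seven eighth-division gridlines per column; relative plates
#' carry a µm scale bar.
#'
#' @param plate A [palm_plate()].
#' @param file Optional output path; the SVG text is also returned.
#' @param config A [plate_config()].
#' @return The SVG document as a single character string (invisibly if `file`
#'   is given).
#' @export
render_svg <- function(plate, file = NULL, config = plate_config()) {
  stopifnot(inherits(plate, "palm_plate"))
  if (!inherits(config, "plate_config")) abort("`config` must be a plate_config().")
  geom <- plate_geometry(plate, config)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_u(geom$canvas[["width"]]), fmt_u(geom$canvas[["height"]]),
            fmt_u(geom$canvas[["width"]]), fmt_u(geom$canvas[["height"]]))
  )
  for (i in seq_along(geom$columns)) {
    col <- geom$columns[[i]]
    out <- c(out, sprintf('<g id="col%d">', i))
    gl <- col$gridlines
    for (j in seq_len(nrow(gl))) {
      out <- c(out, svg_line(gl$x1[j], gl$y[j], gl$x2[j], gl$y[j],
                             id = sprintf("col%d-grid%d", i, gl$k[j]),
                             class = "gridline"))
    }
    out <- c(out, svg_rect(col$body$x, col$body$y, col$body$w, col$body$h,
                           fill = "#000000", id = sprintf("col%d-body", i),
                           class = "body"))
    og <- col$organs
    for (j in seq_len(nrow(og))) {
      out <- c(out, svg_rect(og$x[j], og$y[j], og$w[j], og$h[j],
                             fill = og$color[j],
                             id = sprintf("col%d-organ%d-%s", i, j, og$organ[j]),
                             class = "organ"))
    }
    out <- c(out, svg_text(col$x0 + geom$col_width / 2,
                           config$margin + config$axis_length +
                             1.6 * config$font_size,
                           plate$patterns[[i]]$taxon,
                           id = sprintf("col%d-label", i), class = "label",
                           size = config$font_size))
    out <- c(out, "</g>")
  }
  if (plate$mode == "relative") {
    sb_len <- config$scale_bar_um * geom$units_per_um
    x1 <- config$margin
    y <- geom$canvas[["height"]] - config$margin / 2
    out <- c(out,
             svg_line(x1, y, x1 + sb_len, y, id = "scalebar",
                      class = "scalebar", stroke = "#000000", width = 2),
             svg_text(x1 + sb_len / 2, y - 4,
                      sprintf("%g um", config$scale_bar_um),
                      id = "scalebar-label", class = "scalebar-label",
                      size = 0.8 * config$font_size))
  }
  # legend: palette organs actually present, in palette order
  present <- unique(unlist(map(plate$patterns, function(p) p$bars$organ)))
  leg <- intersect(names(config$palette), present)
  leg <- c(leg, setdiff(present, names(config$palette)))
  for (j in seq_along(leg)) {
    lx <- config$margin
    ly <- geom$canvas[["height"]] - config$margin - 2 -
      (length(leg) - j) * (config$font_size + 2)
    out <- c(out,
             svg_rect(lx, ly - 0.75 * config$font_size,
                      0.75 * config$font_size, 0.75 * config$font_size,
                      fill = organ_color(leg[j], config$palette),
                      id = sprintf("legend-swatch-%s", leg[j]),
                      class = "legend"),
             svg_text(lx + config$font_size, ly, gsub("_", " ", leg[j]),
                      id = sprintf("legend-label-%s", leg[j]),
                      class = "legend-label", size = 0.8 * config$font_size,
                      anchor = "start"))
  }
  out <- c(out, "</svg>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}

#' @describeIn palm_plate ggplot2 view of a plate (non-deterministic rendering
#'   backend; the contract output is [render_svg()]).
#' @param object A `palm_plate`.
#' @param ... Ignored.
#' @method autoplot palm_plate
#' @export
autoplot.palm_plate <- function(object, ...) {
  config <- plate_config()
  geom <- plate_geometry(object, config)
  organs <- bind_rows(map(geom$columns, "organs"))
  bodies <- bind_rows(map(geom$columns, function(c) c$body))
  grids <- bind_rows(map(geom$columns, "gridlines"))
  labels <- tibble(x = map_dbl(geom$columns, function(c) c$x0) +
                     geom$col_width / 2,
                   y = config$margin + config$axis_length +
                     1.6 * config$font_size,
                   taxon = map_chr(geom$columns, "taxon"))
  fill_levels <- unique(organs$organ)
  pal <- setNames(organ_color(fill_levels, config$palette), fill_levels)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = bodies,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                    ymin = .data$y, ymax = .data$y + .data$h),
                       fill = "black")
  if (nrow(grids) > 0) {
    p <- p + ggplot2::geom_segment(
      data = grids,
      ggplot2::aes(x = .data$x1, xend = .data$x2, y = .data$y, yend = .data$y),
      colour = "grey60", linewidth = 0.3)
  }
  if (nrow(organs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = organs,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h,
                   fill = .data$organ)) +
      ggplot2::scale_fill_manual(values = pal)
  }
  p + ggplot2::geom_text(data = labels,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$taxon),
                         size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "organ")
}
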