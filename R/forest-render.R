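# Deterministic forest-plot renderer.
#
# SVG is written directly (fixed element order, fixed number formatting) so
# that identical specs produce byte-identical files — the golden-file
# contract. Every data-carrying glyph also records its data-scale
# coordinates in data-* attributes, and axis ticks carry data-value, so a
# reader can verify glyph geometry in data coordinates by parsing the file.

forest_layout <- function(spec, width) {
  n_study <- nrow(spec$study_rows)
  n_summary <- nrow(spec$summary_rows)
  row_h <- 28
  top <- 34                      # header row for the axis label
  sep_gap <- 10                  # gap + separator between study and summary blocks
  axis_h <- 42
  ann_h <- if (nzchar(spec$annotation)) 22 else 0
  list(
    width = width, row_h = row_h, top = top, sep_gap = sep_gap,
    panel_x0 = 0.42 * width, panel_x1 = width - 30, label_x = 12,
    n_study = n_study, n_summary = n_summary,
    study_y = function(i) top + (i - 0.5) * row_h,
    summary_y = function(j) top + n_study * row_h + sep_gap + (j - 0.5) * row_h,
    axis_y = top + (n_study + n_summary) * row_h + sep_gap + 18,
    height = ceiling(top + (n_study + n_summary) * row_h + sep_gap + axis_h + ann_h)
  )
}

forest_transform <- function(spec, layout) {
  tr <- if (spec$axis$scale == "log") log else identity
  vals <- c(
    spec$study_rows$ci_lower, spec$study_rows$ci_upper,
    spec$summary_rows$lower, spec$summary_rows$upper,
    spec$summary_rows$line_lower, spec$summary_rows$line_upper,
    spec$axis$tick_values, spec$axis$reference_line
  )
  tvals <- tr(vals[is.finite(vals) & !is.na(vals)])
  tmin <- min(tvals); tmax <- max(tvals)
  if (tmax - tmin < 1e-12) { tmin <- tmin - 1; tmax <- tmax + 1 }
  pad <- 0.02 * (tmax - tmin)
  tmin <- tmin - pad; tmax <- tmax + pad
  function(v) {
    layout$panel_x0 +
      (tr(v) - tmin) / (tmax - tmin) * (layout$panel_x1 - layout$panel_x0)
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

px <- function(x) fmt_num(x, 2)        # pixel coordinates
dv <- function(x) sprintf("%.10g", x)  # data-scale attribute values

svg_forest <- function(spec, width = 820) {
  validate_forest_spec(spec)
  lay <- forest_layout(spec, width)
  map <- forest_transform(spec, lay)
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
      lay$width, lay$height, lay$width, lay$height)
  add('<style>text{font-family:Helvetica,Arial,sans-serif;font-size:12px;fill:#000}.row-label{text-anchor:start}.summary-label{font-weight:bold}.tick-label{text-anchor:middle;font-size:11px}.axis-label{text-anchor:middle;font-weight:bold}.heterogeneity{font-size:11px;font-style:italic}</style>')
  add('<rect class="background" x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
      lay$width, lay$height)

  # reference line spans the glyph area
  y_glyph_bottom <- lay$axis_y - 10
  ref <- spec$axis$reference_line
  add('<line class="reference-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-dasharray="4,3" stroke-width="1" data-value="%s"/>',
      px(map(ref)), px(lay$top - 4), px(map(ref)), px(y_glyph_bottom), dv(ref))

  # axis label header
  add('<text class="axis-label" x="%s" y="%s">%s</text>',
      px((lay$panel_x0 + lay$panel_x1) / 2), px(lay$top - 14),
      xml_escape(spec$axis$label))

  # study rows: CI line + weight-proportional square, label at left
  max_w <- max(spec$study_rows$weight)
  max_side <- 16
  for (i in seq_len(nrow(spec$study_rows))) {
    r <- spec$study_rows[i, ]
    y <- lay$study_y(i)
    add('<text class="row-label" x="%s" y="%s">%s</text>',
        px(lay$label_x), px(y + 4), xml_escape(r$label))
    add('<line class="study-ci" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1" data-lower="%s" data-upper="%s"/>',
        px(map(r$ci_lower)), px(y), px(map(r$ci_upper)), px(y),
        dv(r$ci_lower), dv(r$ci_upper))
    side <- max_side * sqrt(r$weight / max_w)
    add('<rect class="study-square" x="%s" y="%s" width="%s" height="%s" fill="#2b2b2b" data-effect="%s" data-weight="%s"/>',
        px(map(r$effect) - side / 2), px(y - side / 2), px(side), px(side),
        dv(r$effect), dv(r$weight))
  }

  # separator between studies and summaries
  y_sep <- lay$top + lay$n_study * lay$row_h + lay$sep_gap / 2
  add('<line class="separator" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1"/>',
      px(lay$label_x), px(y_sep), px(lay$panel_x1), px(y_sep))

  diamond_points <- function(lower, center, upper, y, h) {
    paste(
      sprintf("%s,%s", px(map(lower)), px(y)),
      sprintf("%s,%s", px(map(center)), px(y - h)),
      sprintf("%s,%s", px(map(upper)), px(y)),
      sprintf("%s,%s", px(map(center)), px(y + h))
    )
  }

  for (j in seq_len(nrow(spec$summary_rows))) {
    r <- spec$summary_rows[j, ]
    y <- lay$summary_y(j)
    h <- 0.30 * lay$row_h
    add('<text class="row-label summary-label" x="%s" y="%s">%s</text>',
        px(lay$label_x), px(y + 4), xml_escape(r$label))
    if (r$glyph == "diamond" || r$glyph == "extended_diamond") {
      add('<polygon class="summary-diamond" points="%s" fill="#000000" data-lower="%s" data-center="%s" data-upper="%s"/>',
          diamond_points(r$lower, r$center, r$upper, y, h),
          dv(r$lower), dv(r$center), dv(r$upper))
      if (r$glyph == "extended_diamond") {
        add('<line class="pi-extension" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1.5" data-lower="%s" data-upper="%s"/>',
            px(map(r$line_lower)), px(y), px(map(r$lower)), px(y),
            dv(r$line_lower), dv(r$line_upper))
        add('<line class="pi-extension" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1.5" data-lower="%s" data-upper="%s"/>',
            px(map(r$upper)), px(y), px(map(r$line_upper)), px(y),
            dv(r$line_lower), dv(r$line_upper))
      }
    } else if (r$glyph == "hollow_diamond") {
      add('<polygon class="pi-hollow-diamond" points="%s" fill="none" stroke="#000000" stroke-width="1.5" data-lower="%s" data-center="%s" data-upper="%s"/>',
          diamond_points(r$lower, r$center, r$upper, y, h),
          dv(r$lower), dv(r$center), dv(r$upper))
    } else if (r$glyph == "rectangle") {
      # the PI rectangle: a region, deliberately without a centre tick
      rh <- 0.6 * lay$row_h
      add('<rect class="pi-rectangle" x="%s" y="%s" width="%s" height="%s" fill="#6b6b6b" data-lower="%s" data-upper="%s"/>',
          px(map(r$lower)), px(y - rh / 2),
          px(map(r$upper) - map(r$lower)), px(rh),
          dv(r$lower), dv(r$upper))
    } else {
      abort_data(sprintf("Unknown summary glyph '%s'.", r$glyph))
    }
  }

  # axis line, ticks, tick labels
  add('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1"/>',
      px(lay$panel_x0), px(lay$axis_y), px(lay$panel_x1), px(lay$axis_y))
  for (tv in spec$axis$tick_values) {
    add('<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1" data-value="%s"/>',
        px(map(tv)), px(lay$axis_y), px(map(tv)), px(lay$axis_y + 5), dv(tv))
    add('<text class="tick-label" x="%s" y="%s">%s</text>',
        px(map(tv)), px(lay$axis_y + 17), sprintf("%g", tv))
  }

  if (nzchar(spec$annotation)) {
    add('<text class="heterogeneity" x="%s" y="%s">%s</text>',
        px(lay$label_x), px(lay$axis_y + 34), xml_escape(spec$annotation))
  }

  add('</svg>')
  out
}

#' Render a forest plot to SVG or PNG
#'
#' SVG output is fully deterministic: the same spec always yields a
#' byte-identical file, suitable for golden-file comparison. Study squares
#' have area proportional to their normalized pooling weight; the
#' prediction-interval rectangle, hollow diamond, or extension lines use a
#' different SVG element class than the summary diamond, so the two
#' interval types are never drawn with the same symbol. Glyphs carry their
#' data-scale coordinates as `data-*` attributes. PNG output draws
#' [autoplot.forest_spec()] through the png device.
#'
#' The spec is validated (including positivity on a log axis) before any
#' file is written.
#'
#' @param spec A `forest_spec`.
#' @param path Output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @param width Plot width in pixels.
#' @return `path`, invisibly.
#' @export
render <- function(spec, path, format = c("svg", "png"), width = 820) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "forest_spec"))
  if (format == "svg") {
    lines <- svg_forest(spec, width = width)   # validates before writing
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    validate_forest_spec(spec)
    p <- autoplot(spec)
    lay <- forest_layout(spec, width)
    grDevices::png(path, width = width, height = lay$height, res = 96)
    on.exit(grDevices::dev.off())
    print(p)
  }
  invisible(path)
}

#' Plot a forest spec with ggplot2
#'
#' A ggplot2 rendering of the same specification [render()] writes to SVG:
#' study squares sized by weight with confidence lines, the summary
#' diamond, and the prediction interval in the style the spec carries.
#'
#' @param object A `forest_spec`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot forest_spec
#' @export
autoplot.forest_spec <- function(object, ...) {
  spec <- object
  n_study <- nrow(spec$study_rows)
  n_summary <- nrow(spec$summary_rows)
  gap <- 0.6
  study_df <- dplyr::mutate(
    spec$study_rows,
    y = n_study + n_summary + gap + 1 - dplyr::row_number()
  )
  summary_df <- dplyr::mutate(
    spec$summary_rows,
    y = n_summary + 1 - dplyr::row_number()
  )
  labels_df <- dplyr::bind_rows(
    dplyr::select(study_df, "label", "y"),
    dplyr::select(summary_df, "label", "y")
  )

  diamond_df <- dplyr::filter(
    summary_df, .data$glyph %in% c("diamond", "extended_diamond", "hollow_diamond")
  )
  diamond_poly <- purrr::pmap_dfr(
    list(diamond_df$lower, diamond_df$center, diamond_df$upper,
         diamond_df$y, diamond_df$glyph, seq_len(nrow(diamond_df))),
    function(lo, ce, up, y, glyph, id) {
      tibble::tibble(
        x = c(lo, ce, up, ce), y = c(y, y + 0.25, y, y - 0.25),
        id = id, hollow = glyph == "hollow_diamond"
      )
    }
  )
  rect_df <- dplyr::filter(summary_df, .data$glyph == "rectangle")
  ext_df <- dplyr::filter(summary_df, .data$glyph == "extended_diamond")

  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(
      xintercept = spec$axis$reference_line, linetype = "dashed",
      colour = "grey55"
    ) +
    ggplot2::geom_segment(
      data = study_df,
      ggplot2::aes(x = .data$ci_lower, xend = .data$ci_upper,
                   y = .data$y, yend = .data$y),
      linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = study_df,
      ggplot2::aes(x = .data$effect, y = .data$y, size = sqrt(.data$weight)),
      shape = 15, show.legend = FALSE
    ) +
    ggplot2::scale_size_area(max_size = 5)
  if (nrow(diamond_poly) > 0) {
    solid <- dplyr::filter(diamond_poly, !.data$hollow)
    hollow <- dplyr::filter(diamond_poly, .data$hollow)
    if (nrow(solid) > 0) {
      p <- p + ggplot2::geom_polygon(
        data = solid,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
        fill = "black"
      )
    }
    if (nrow(hollow) > 0) {
      p <- p + ggplot2::geom_polygon(
        data = hollow,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
        fill = NA, colour = "black", linewidth = 0.6
      )
    }
  }
  if (nrow(rect_df) > 0) {
    p <- p + ggplot2::geom_rect(
      data = rect_df,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = .data$y - 0.3, ymax = .data$y + 0.3),
      fill = "grey40"
    )
  }
  if (nrow(ext_df) > 0) {
    p <- p + ggplot2::geom_segment(
      data = ext_df,
      ggplot2::aes(x = .data$line_lower, xend = .data$line_upper,
                   y = .data$y, yend = .data$y),
      linewidth = 0.7
    )
  }
  p <- p +
    ggplot2::scale_y_continuous(
      breaks = labels_df$y, labels = labels_df$label, limits = c(0.4, NA)
    ) +
    ggplot2::labs(x = spec$axis$label, y = NULL, caption = spec$annotation) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
  if (spec$axis$scale == "log") {
    p <- p + ggplot2::scale_x_log10(breaks = spec$axis$tick_values)
  } else {
    p <- p + ggplot2::scale_x_continuous(breaks = spec$axis$tick_values)
  }
  p
}
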