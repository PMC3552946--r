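# Helpers for inspecting rendered SVGs: all glyphs carry their data-scale
# coordinates in data-* attributes, and the pixel mapping is recovered
# independently from the axis ticks.

svg_nodes <- function(doc, class) {
  xml2::xml_find_all(doc, sprintf("//*[@class='%s']", class))
}

# Recover data coordinates from pixel positions using the axis ticks.
pixel_to_data <- function(doc, log_axis = TRUE) {
  ticks <- svg_nodes(doc, "tick")
  px <- as.numeric(xml2::xml_attr(ticks, "x1"))
  val <- as.numeric(xml2::xml_attr(ticks, "data-value"))
  tv <- if (log_axis) log(val) else val
  slope <- (tv[length(tv)] - tv[1]) / (px[length(px)] - px[1])
  function(p) {
    t <- tv[1] + slope * (p - px[1])
    if (log_axis) exp(t) else t
  }
}

test_that("forest specs carry the expected rows for every style", {
  fx <- fixture_analysis()
  spec <- fx$spec
  expect_equal(nrow(spec$study_rows), 8)
  expect_equal(nrow(spec$summary_rows), 2)
  expect_equal(spec$summary_rows$label[1], "Total expectation (95% CI)")
  expect_equal(spec$summary_rows$label[2], "95% prediction interval")
  expect_equal(spec$summary_rows$glyph, c("diamond", "rectangle"))
  expect_true(is.na(spec$summary_rows$center[2]))
  expect_equal(spec$summary_rows$lower[2], exp(fx$pi$lower), tolerance = 1e-12)
  expect_equal(spec$summary_rows$upper[2], exp(fx$pi$upper), tolerance = 1e-12)

  none <- build_forest_spec(fx$studies, fx$pool, pi_style = "none")
  expect_equal(nrow(none$summary_rows), 1)
  expect_equal(none$summary_rows$glyph, "diamond")

  hollow <- build_forest_spec(fx$studies, fx$pool, fx$pi, "hollow_diamond")
  expect_equal(hollow$summary_rows$glyph, c("diamond", "hollow_diamond"))

  ext <- build_forest_spec(fx$studies, fx$pool, fx$pi, "extended_diamond")
  expect_equal(nrow(ext$summary_rows), 1)
  expect_equal(ext$summary_rows$glyph, "extended_diamond")
  expect_equal(ext$summary_rows$lower, exp(fx$pool$ci[["lower"]]), tolerance = 1e-12)
  expect_equal(ext$summary_rows$line_lower, exp(fx$pi$lower), tolerance = 1e-12)
  expect_equal(ext$summary_rows$line_upper, exp(fx$pi$upper), tolerance = 1e-12)

  expect_error(build_forest_spec(fx$studies, fx$pool, pi = NULL, "rectangle"),
               class = "metapi_config_error")
})

test_that("ratio-scale axes are logarithmic with the reference at 1", {
  fx <- fixture_analysis()
  expect_equal(fx$spec$axis$scale, "log")
  expect_equal(fx$spec$axis$reference_line, 1.0)
  expect_true(all(fx$spec$axis$tick_values > 0))

  lin <- pool_random(tibble::tibble(effect = c(0, 1), se = c(0.5, 0.5),
                                    scale_tag = "linear"))
  spec <- build_forest_spec(pool = lin, pi = NULL, pi_style = "none")
  expect_equal(spec$axis$scale, "linear")
  expect_equal(spec$axis$reference_line, 0.0)
})

test_that("rendering is byte-identical across repeated runs for all styles", {
  for (style in c("rectangle", "hollow_diamond", "extended_diamond")) {
    fx <- fixture_analysis(style)
    p1 <- withr::local_tempfile(fileext = ".svg")
    p2 <- withr::local_tempfile(fileext = ".svg")
    render(fx$spec, p1)
    render(fx$spec, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("the rectangle glyph sits on its own labeled row and spans the PI", {
  fx <- fixture_analysis()
  path <- withr::local_tempfile(fileext = ".svg")
  render(fx$spec, path)
  doc <- xml2::read_xml(path)

  rects <- svg_nodes(doc, "pi-rectangle")
  expect_length(rects, 1)
  labels <- xml2::xml_text(svg_nodes(doc, "row-label summary-label"))
  expect_true("95% prediction interval" %in% labels)

  # declared data coordinates match the prediction interval
  expect_equal(as.numeric(xml2::xml_attr(rects, "data-lower")),
               exp(fx$pi$lower), tolerance = 1e-8)
  expect_equal(as.numeric(xml2::xml_attr(rects, "data-upper")),
               exp(fx$pi$upper), tolerance = 1e-8)

  # pixel geometry, inverted through the axis ticks, recovers the same span
  inv <- pixel_to_data(doc, log_axis = TRUE)
  x <- as.numeric(xml2::xml_attr(rects, "x"))
  w <- as.numeric(xml2::xml_attr(rects, "width"))
  expect_equal(inv(x), exp(fx$pi$lower), tolerance = 1e-2)
  expect_equal(inv(x + w), exp(fx$pi$upper), tolerance = 1e-2)

  # the PI glyph never shares the CI diamond's symbol class
  expect_length(svg_nodes(doc, "summary-diamond"), 1)
  for (style in c("hollow_diamond", "extended_diamond")) {
    fx2 <- fixture_analysis(style)
    p2 <- withr::local_tempfile(fileext = ".svg")
    render(fx2$spec, p2)
    doc2 <- xml2::read_xml(p2)
    pi_class <- if (style == "hollow_diamond") "pi-hollow-diamond" else "pi-extension"
    expect_gt(length(svg_nodes(doc2, pi_class)), 0)
    expect_length(svg_nodes(doc2, "pi-rectangle"), 0)
  }
})

test_that("tick pixel positions are logarithmically spaced on a log axis", {
  fx <- fixture_analysis()
  path <- withr::local_tempfile(fileext = ".svg")
  render(fx$spec, path)
  doc <- xml2::read_xml(path)
  ticks <- svg_nodes(doc, "tick")
  px <- as.numeric(xml2::xml_attr(ticks, "x1"))
  lv <- log(as.numeric(xml2::xml_attr(ticks, "data-value")))
  # pixel position must be an affine function of log(value)
  fit <- stats::lm(px ~ lv)
  expect_lt(max(abs(stats::residuals(fit))), 0.02)
})

test_that("study squares scale with the square root of their weights", {
  studies <- tibble::tibble(
    label = c("big", "small1", "small2"),
    effect = c(0.1, 0.2, 0.3), se = c(1, sqrt(2), sqrt(2))
  )
  pool <- pool_fixed(studies)
  expect_equal(unname(pool$weights), c(0.5, 0.25, 0.25), tolerance = 1e-12)
  spec <- build_forest_spec(studies, pool, pi_style = "none")
  path <- withr::local_tempfile(fileext = ".svg")
  render(spec, path)
  doc <- xml2::read_xml(path)
  sides <- as.numeric(xml2::xml_attr(svg_nodes(doc, "study-square"), "width"))
  expect_equal(sides[1] / sides[2], sqrt(2), tolerance = 1e-2)
  expect_equal(sides[2], sides[3], tolerance = 1e-6)
})

test_that("an unplottable spec errors before any file is written", {
  fx <- fixture_analysis()
  bad <- fx$spec
  bad$study_rows$effect[1] <- 0.2
  bad$study_rows$ci_lower[1] <- -0.5  # impossible on a log axis
  path <- withr::local_tempfile(fileext = ".svg")
  expect_error(render(bad, path), "log axis", class = "metapi_data_error")
  expect_false(file.exists(path))
})

test_that("the inflation demo shrinks study CIs but preserves the PI limit", {
  fx <- fixture_analysis()
  base <- rectangle_rationale_demo(fx$studies, inflation = 1)
  expect_equal(base$study_rows, fx$spec$study_rows, tolerance = 1e-12)

  blown <- rectangle_rationale_demo(fx$studies, inflation = 1000)
  width <- function(s) log(s$study_rows$ci_upper) - log(s$study_rows$ci_lower)
  expect_true(all(width(blown) < 0.01 * width(base)))

  # with within-study error gone, the PI approaches center +/- t * tau
  tau <- sqrt(fx$pool$tau2)
  huge <- rectangle_rationale_demo(fx$studies, inflation = 1e6)
  rect <- huge$summary_rows[huge$summary_rows$glyph == "rectangle", ]
  expect_equal(log(rect$upper) - log(rect$lower),
               2 * qt(0.975, fx$pool$k - 2) * tau, tolerance = 1e-4)

  expect_error(rectangle_rationale_demo(fx$studies, inflation = 0.5),
               class = "metapi_config_error")
})

test_that("forest specs round-trip through JSON", {
  for (style in c("rectangle", "extended_diamond", "none")) {
    fx <- fixture_analysis()
    spec <- build_forest_spec(fx$studies, fx$pool,
                              if (style == "none") NULL else fx$pi, style)
    path <- withr::local_tempfile(fileext = ".json")
    write_forest_spec(spec, path)
    back <- read_forest_spec(path)
    expect_equal(back$study_rows, spec$study_rows, tolerance = 1e-12)
    expect_equal(back$summary_rows, spec$summary_rows, tolerance = 1e-12)
    expect_equal(back$axis, spec$axis, tolerance = 1e-12)
    expect_equal(back$pi_style, spec$pi_style)
  }
})

test_that("autoplot returns a ggplot and png rendering writes a file", {
  fx <- fixture_analysis()
  p <- autoplot(fx$spec)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  render(fx$spec, path, format = "png")
  expect_true(file.size(path) > 0)
})
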