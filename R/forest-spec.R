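#' Build a declarative forest-plot specification
#'
#' Assembles everything a forest plot displays into a plain data structure:
#' one row per study (square sized by pooling weight, line for the
#' study-level confidence interval), a summary diamond for the pooled
#' effect and its confidence interval, and — for random-effects analyses —
#' the prediction interval in one of three styles:
#' \describe{
#'   \item{`rectangle`}{the recommended style: an additional, separate
#'     summary row labelled "95\% prediction interval" carrying a rectangle
#'     spanning the interval. The rectangle is the limiting shape of the
#'     study squares of a set of infinitely large studies, so it depicts
#'     between-study dispersion with a glyph that cannot be mistaken for
#'     the confidence-interval diamond.}
#'   \item{`hollow_diamond`}{a second, unfilled diamond spanning the
#'     prediction interval (Higgins-style).}
#'   \item{`extended_diamond`}{the pooled diamond with horizontal lines
#'     extending to the prediction-interval bounds (Riley-style).}
#'   \item{`none`}{confidence-interval diamond only.}
#' }
#' Ratio-scale records (`scale_tag = "log_ratio"`) are drawn on a log axis
#' with the reference line at 1; linear records on a linear axis with the
#' reference at 0.
#'
#' @param studies Study records; defaults to the studies inside `pool`.
#' @param pool A `pool_result` from [pool_fixed()] or [pool_random()].
#' @param pi A `prediction_interval`, required unless `pi_style = "none"`.
#' @param pi_style One of `"rectangle"` (default), `"hollow_diamond"`,
#'   `"extended_diamond"`, `"none"`.
#' @return A `forest_spec` object: tibbles `study_rows` and `summary_rows`,
#'   an `axis` description, the `pi_style`, and a heterogeneity annotation.
#' @export
build_forest_spec <- function(studies = pool$studies, pool, pi = NULL,
                              pi_style = c("rectangle", "hollow_diamond",
                                           "extended_diamond", "none")) {
  pi_style <- match.arg(pi_style)
  stopifnot(inherits(pool, "pool_result"))
  studies <- as_study_records(studies)
  if (nrow(studies) != pool$k) {
    abort_data("`studies` does not match the pooled result (different number of studies).")
  }
  if (pi_style != "none" && is.null(pi)) {
    abort_config(sprintf(
      "pi_style = \"%s\" requires a prediction interval; pass `pi` or use pi_style = \"none\".",
      pi_style
    ))
  }
  if (!is.null(pi)) stopifnot(inherits(pi, "prediction_interval"))

  log_axis <- all(studies$scale_tag == "log_ratio")
  disp <- if (log_axis) exp else identity

  z <- z_quantile(pool$level)
  study_rows <- tibble::tibble(
    label = studies$label,
    effect = disp(studies$effect),
    ci_lower = disp(studies$effect - z * studies$se),
    ci_upper = disp(studies$effect + z * studies$se),
    weight = unname(pool$weights)
  )

  summary_rows <- tibble::tibble(
    label = sprintf("Total expectation (%g%% CI)", 100 * pool$level),
    glyph = "diamond",
    center = disp(pool$pooled),
    lower = disp(pool$ci[["lower"]]),
    upper = disp(pool$ci[["upper"]]),
    line_lower = NA_real_,
    line_upper = NA_real_
  )
  if (pi_style == "rectangle") {
    summary_rows <- dplyr::bind_rows(summary_rows, tibble::tibble(
      label = sprintf("%g%% prediction interval", 100 * pi$level),
      glyph = "rectangle",
      center = NA_real_,
      lower = disp(pi$lower), upper = disp(pi$upper),
      line_lower = NA_real_, line_upper = NA_real_
    ))
  } else if (pi_style == "hollow_diamond") {
    summary_rows <- dplyr::bind_rows(summary_rows, tibble::tibble(
      label = sprintf("%g%% prediction interval", 100 * pi$level),
      glyph = "hollow_diamond",
      center = disp(pi$center),
      lower = disp(pi$lower), upper = disp(pi$upper),
      line_lower = NA_real_, line_upper = NA_real_
    ))
  } else if (pi_style == "extended_diamond") {
    # single merged row: diamond extent = CI, line extent = PI
    summary_rows$glyph <- "extended_diamond"
    summary_rows$line_lower <- disp(pi$lower)
    summary_rows$line_upper <- disp(pi$upper)
  }

  annotation <- if (!is.na(pool$q_stat)) {
    sprintf(
      "Heterogeneity: tau = %.2f, I² = %.0f%%, Q = %.2f (df = %d)",
      sqrt(pool$tau2), 100 * pool$i2, pool$q_stat, pool$q_df
    )
  } else {
    ""
  }

  axis <- list(
    scale = if (log_axis) "log" else "linear",
    reference_line = if (log_axis) 1.0 else 0.0,
    tick_values = forest_ticks(
      c(study_rows$ci_lower, study_rows$ci_upper,
        summary_rows$lower, summary_rows$upper,
        summary_rows$line_lower, summary_rows$line_upper,
        if (log_axis) 1.0 else 0.0),
      log_axis
    ),
    label = if (log_axis) "Odds ratio" else "Effect"
  )

  new_forest_spec(study_rows, summary_rows, axis, pi_style, annotation)
}

new_forest_spec <- function(study_rows, summary_rows, axis, pi_style, annotation) {
  spec <- structure(
    list(
      study_rows = study_rows, summary_rows = summary_rows,
      axis = axis, pi_style = pi_style, annotation = annotation
    ),
    class = "forest_spec"
  )
  validate_forest_spec(spec)
  spec
}

validate_forest_spec <- function(spec) {
  sr <- spec$study_rows
  if (any(sr$weight < 0)) abort_data("Forest spec: weights must be non-negative.")
  if (any(sr$ci_lower > sr$effect | sr$effect > sr$ci_upper)) {
    abort_data("Forest spec: study rows must satisfy ci_lower <= effect <= ci_upper.")
  }
  sm <- spec$summary_rows
  ok <- is.na(sm$center) | (sm$lower <= sm$center & sm$center <= sm$upper)
  if (!all(ok)) {
    abort_data("Forest spec: summary rows must satisfy lower <= center <= upper.")
  }
  if (spec$axis$scale == "log") {
    vals <- c(sr$effect, sr$ci_lower, sr$ci_upper, sm$center, sm$lower,
              sm$upper, sm$line_lower, sm$line_upper, spec$axis$tick_values,
              spec$axis$reference_line)
    if (any(vals <= 0, na.rm = TRUE)) {
      abort_data("Forest spec: a log axis requires all plotted values to be positive.")
    }
  }
  invisible(spec)
}

# Tick placement: 1-2-5 per decade on a log axis, pretty() on linear.
forest_ticks <- function(values, log_axis) {
  values <- values[is.finite(values)]
  if (log_axis) {
    lo <- min(values); hi <- max(values)
    candidates <- as.vector(outer(c(1, 2, 5), 10^(-4:4)))
    ticks <- candidates[candidates >= lo & candidates <= hi]
    if (length(ticks) < 2) {
      ticks <- sort(unique(signif(exp(pretty(log(c(lo, hi)), n = 4)), 2)))
    }
    ticks
  } else {
    pretty(values, n = 6)
  }
}

#' @export
print.forest_spec <- function(x, ...) {
  cat(sprintf(
    "Forest plot spec: %d study rows, %d summary row(s), %s axis, pi_style = \"%s\"\n",
    nrow(x$study_rows), nrow(x$summary_rows), x$axis$scale, x$pi_style
  ))
  invisible(x)
}

#' Pedagogical demo of the rectangle glyph's rationale
#'
#' Illustrates why the prediction interval is drawn as a rectangle: imagine
#' the same meta-analysis with ever larger studies. Each study's standard
#' error is divided by `inflation`, so the per-study confidence lines
#' shrink toward points while the squares — whose spread reflects genuine
#' between-study dispersion — remain. In the limit the merged squares form
#' a rectangle. The between-study variance is held at its original
#' DerSimonian-Laird estimate, and the interval's pooled standard error is
#' taken from the plain inverse-variance combination, which vanishes with
#' the within-study errors; the prediction interval therefore converges to
#' `center +/- t * tau`, the pure between-study dispersion.
#'
#' @param studies Study records.
#' @param inflation Factor >= 1 by which study precision is inflated.
#' @param level Confidence level, default 0.95.
#' @return A `forest_spec` in the rectangle style.
#' @export
rectangle_rationale_demo <- function(studies, inflation = 1, level = 0.95) {
  if (!is.numeric(inflation) || length(inflation) != 1L ||
      !is.finite(inflation) || inflation < 1) {
    abort_config("`inflation` must be a single number >= 1.")
  }
  studies <- as_study_records(studies)
  tau2 <- pool_random(studies, level = level)$tau2
  inflated <- dplyr::mutate(studies, se = .data$se / inflation)
  pool <- pool_random(inflated, level = level, tau2_override = tau2)
  # the within-study-driven pooled SE (no tau2 in the weights) -> 0 as the
  # studies grow, so the PI tends to the pure between-study band
  se_iv <- pool_fixed(inflated, level = level)$se_pooled
  scale_tag <- if (all(inflated$scale_tag == "log_ratio")) "log_ratio" else "linear"
  pi <- prediction_interval(pool$pooled, se_iv, tau2, pool$k, level = level,
                            scale_tag = scale_tag)
  build_forest_spec(inflated, pool, pi, pi_style = "rectangle")
}

#' Serialize a forest spec to JSON
#'
#' Round-trips with [read_forest_spec()] so a plot can be reproduced
#' exactly from a serialized analysis.
#'
#' @param spec A `forest_spec`.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_forest_spec <- function(spec, path) {
  stopifnot(inherits(spec, "forest_spec"))
  jsonlite::write_json(
    list(
      study_rows = spec$study_rows,
      summary_rows = spec$summary_rows,
      axis = spec$axis,
      pi_style = spec$pi_style,
      annotation = spec$annotation
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_forest_spec
#' @export
read_forest_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  summary_rows <- tibble::as_tibble(raw$summary_rows)
  # columns that were all-null come back logical; restore numeric type
  for (col in c("center", "line_lower", "line_upper")) {
    summary_rows[[col]] <- as.numeric(summary_rows[[col]])
  }
  new_forest_spec(
    study_rows = tibble::as_tibble(raw$study_rows),
    summary_rows = summary_rows,
    axis = list(
      scale = raw$axis$scale,
      reference_line = raw$axis$reference_line,
      tick_values = as.numeric(raw$axis$tick_values),
      label = raw$axis$label
    ),
    pi_style = raw$pi_style,
    annotation = raw$annotation
  )
}
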