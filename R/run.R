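#' Configuration for a full analysis run
#'
#' Validates the options of an end-to-end run (read studies, pool, compute
#' the prediction interval, plot, report). The prediction interval belongs
#' to the random-effects model — it describes the dispersion of true
#' effects, which the fixed-effect model assumes away — so
#' `model = "fixed"` combined with any `pi_style` other than `"none"` is a
#' configuration error, not a warning.
#'
#' @param input Path to a study-table CSV (see [read_study_table()]).
#' @param model `"random"` (default) or `"fixed"`.
#' @param level Confidence/prediction level, default 0.95.
#' @param pi_style Forest-plot style for the prediction interval; defaults
#'   to `"rectangle"` under the random-effects model and `"none"` under
#'   the fixed-effect model.
#' @param report Optional path for the JSON report.
#' @param plot Optional path for the forest plot (extension picks the
#'   format: `.svg` or `.png`).
#' @param verbose Emit progress messages; never changes numeric output.
#' @return A `run_config` object.
#' @export
run_config <- function(input, model = c("random", "fixed"), level = 0.95,
                       pi_style = NULL, report = NULL, plot = NULL,
                       verbose = FALSE) {
  model <- match.arg(model)
  check_level(level)
  pi_style <- pi_style %||% if (model == "random") "rectangle" else "none"
  if (!pi_style %in% c("rectangle", "hollow_diamond", "extended_diamond", "none")) {
    abort_config(sprintf("Unknown pi_style '%s'.", pi_style))
  }
  if (model == "fixed" && pi_style != "none") {
    abort_config(paste(
      "A prediction interval cannot be requested under the fixed-effect model:",
      "it describes between-study dispersion, which that model assumes to be zero.",
      "Use model = \"random\" or pi_style = \"none\"."
    ))
  }
  structure(
    list(input = input, model = model, level = level, pi_style = pi_style,
         report = report, plot = plot, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Run a full meta-analysis pipeline
#'
#' Reads the study table, pools under the configured model, computes the
#' t-based prediction interval (random-effects only), optionally renders
#' the forest plot and writes a JSON report. The report embeds the
#' resolved configuration and the package version so any run can be
#' reproduced from its report alone.
#'
#' @param config A [run_config()].
#' @return The report, invisibly, as a list mirroring the JSON document.
#' @export
run_meta <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  say("Reading study table from %s", config$input)
  studies <- read_study_table(config$input)
  say("Read %d studies", nrow(studies))

  pool <- if (config$model == "random") {
    pool_random(studies, level = config$level)
  } else {
    pool_fixed(studies, level = config$level)
  }
  say("Pooled estimate %.4f (SE %.4f)", pool$pooled, pool$se_pooled)

  pi <- NULL
  if (config$model == "random" && pool$k >= 3) {
    pi <- pi_from_pool(pool)
    say("Prediction interval [%.4f, %.4f] on the analysis scale", pi$lower, pi$upper)
  }

  plot_path <- NULL
  if (!is.null(config$plot)) {
    spec <- build_forest_spec(studies, pool, pi, pi_style = config$pi_style)
    fmt <- if (grepl("\\.png$", config$plot, ignore.case = TRUE)) "png" else "svg"
    render(spec, config$plot, format = fmt)
    plot_path <- config$plot
    say("Forest plot written to %s", plot_path)
  }

  report <- list(
    package = "metapi",
    version = as.character(packageVersion("metapi")),
    config = list(
      input = config$input, model = config$model, level = config$level,
      pi_style = config$pi_style
    ),
    pool = pool_result_json(pool),
    prediction = if (!is.null(pi)) prediction_interval_json(pi),
    plot = plot_path
  )
  if (!is.null(config$report)) {
    jsonlite::write_json(report, config$report, auto_unbox = TRUE,
                         digits = NA, null = "null")
    say("Report written to %s", config$report)
  }
  invisible(report)
}
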