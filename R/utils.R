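# Internal helpers shared across modules.

# Error classes drive CLI exit codes: data errors (bad input tables,
# impossible values) exit 1, configuration errors exit 2.
abort_data <- function(message, ...) {
  abort(message, class = "metapi_data_error", ...)
}

abort_config <- function(message, ...) {
  abort(message, class = "metapi_config_error", ...)
}

# (1 + level)/2 quantiles used throughout; level is the two-sided coverage.
z_quantile <- function(level) qnorm(1 - (1 - level) / 2)
t_quantile <- function(level, df) qt(1 - (1 - level) / 2, df = df)

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    abort_config("`level` must be a single number strictly between 0 and 1.")
  }
  level
}

# Coerce the `studies` argument (any data frame with effect/se columns,
# e.g. the output of study_effects() or simulate_meta()) to the internal
# study-record tibble, validating the invariants: finite effects, strictly
# positive finite standard errors.
as_study_records <- function(studies, arg = "studies") {
  if (!is.data.frame(studies)) {
    abort_data(sprintf("`%s` must be a data frame of study records.", arg))
  }
  missing_cols <- setdiff(c("effect", "se"), names(studies))
  if (length(missing_cols) > 0) {
    abort_data(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(studies)
  if (!"label" %in% names(out)) {
    out$label <- paste("Study", seq_len(nrow(out)))
  }
  if (!"scale_tag" %in% names(out)) {
    out$scale_tag <- "linear"
  }
  if (!is.numeric(out$effect) || !is.numeric(out$se)) {
    abort_data(sprintf("`%s`: `effect` and `se` must be numeric.", arg))
  }
  bad_effect <- which(!is.finite(out$effect))
  if (length(bad_effect) > 0) {
    abort_data(sprintf(
      "`%s`: non-finite effect in row %d.", arg, bad_effect[1]
    ))
  }
  bad_se <- which(!is.finite(out$se) | out$se <= 0)
  if (length(bad_se) > 0) {
    abort_data(sprintf(
      "`%s`: standard error must be positive and finite (row %d).",
      arg, bad_se[1]
    ))
  }
  out[, c("label", "effect", "se", "scale_tag")]
}

# Deterministic number formatting for serialized output (SVG, JSON filenames).
fmt_num <- function(x, digits = 3) {
  sprintf(paste0("%.", digits, "f"), x)
}
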