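#' Log odds ratios from 2x2 tables
#'
#' Converts per-study 2x2 counts (events / totals in a treatment and a
#' control arm) to log odds ratios with large-sample standard errors,
#' the analysis-scale inputs for pooling. For a table with cells
#' a (events, treatment), b (non-events, treatment), c (events, control),
#' d (non-events, control):
#' \deqn{\hat\theta = \ln\frac{a d}{b c}, \qquad
#'       \widehat{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}.}
#'
#' Tables containing a zero cell have no finite log odds ratio. Under the
#' default `"haldane"` policy the Haldane-Anscombe correction adds 0.5 to
#' all four cells of the affected tables only; `"strict"` raises an error
#' instead. Tables with a zero margin (no events in either arm, or no
#' non-events in either arm) carry no information about the odds ratio and
#' are always an error.
#'
#' @param events_trt,total_trt,events_ctl,total_ctl Integer vectors of
#'   event counts and arm sizes, recycled to a common length.
#' @param label Optional study labels; defaults to `"Study i"`.
#' @param zero_cell_policy `"haldane"` (default) or `"strict"`.
#' @return A tibble of study records with columns `label`, `effect`
#'   (log odds ratio), `se`, and `scale_tag = "log_ratio"`.
#' @examples
#' log_odds_ratio(10, 100, 20, 100)
#' @export
log_odds_ratio <- function(events_trt, total_trt, events_ctl, total_ctl,
                           label = NULL,
                           zero_cell_policy = c("haldane", "strict")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  n <- max(length(events_trt), length(total_trt),
           length(events_ctl), length(total_ctl))
  a <- rep_len(as.numeric(events_trt), n)
  nt <- rep_len(as.numeric(total_trt), n)
  c_ <- rep_len(as.numeric(events_ctl), n)
  nc <- rep_len(as.numeric(total_ctl), n)
  label <- label %||% paste("Study", seq_len(n))
  label <- rep_len(as.character(label), n)

  validate_counts <- function(x, what) {
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      abort_data(sprintf(
        "Invalid %s for study '%s': counts must be non-negative.",
        what, label[bad[1]]
      ))
    }
  }
  validate_counts(a, "events_trt")
  validate_counts(nt, "total_trt")
  validate_counts(c_, "events_ctl")
  validate_counts(nc, "total_ctl")
  if (any(nt <= 0) || any(nc <= 0)) {
    bad <- which(nt <= 0 | nc <= 0)[1]
    abort_data(sprintf("Study '%s': arm totals must be positive.", label[bad]))
  }
  if (any(a > nt) || any(c_ > nc)) {
    bad <- which(a > nt | c_ > nc)[1]
    abort_data(sprintf(
      "Study '%s': events exceed the arm total.", label[bad]
    ))
  }

  b <- nt - a
  d <- nc - c_

  no_info <- (a + c_ == 0) | (b + d == 0)
  if (any(no_info)) {
    abort_data(sprintf(
      "Study '%s': zero events (or zero non-events) in both arms; the odds ratio carries no information.",
      label[which(no_info)[1]]
    ))
  }

  has_zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  if (any(has_zero) && zero_cell_policy == "strict") {
    abort_data(sprintf(
      "Study '%s' contains a zero cell (zero_cell_policy = \"strict\").",
      label[which(has_zero)[1]]
    ))
  }
  # Haldane-Anscombe: +0.5 to every cell of affected tables only.
  adj <- ifelse(has_zero, 0.5, 0)
  a <- a + adj; b <- b + adj; c_ <- c_ + adj; d <- d + adj

  tibble::tibble(
    label = label,
    effect = log((a * d) / (b * c_)),
    se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d),
    scale_tag = "log_ratio"
  )
}

#' Build study records from a study table
#'
#' Accepts either of the two supported study-table schemas and returns a
#' tidy tibble of analysis-scale study records:
#' \itemize{
#'   \item counts schema: `label`, `events_trt`, `total_trt`, `events_ctl`,
#'     `total_ctl` — rows are converted via [log_odds_ratio()];
#'   \item effects schema: `label`, `effect`, `se` (optionally `scale_tag`)
#'     — a pass-through for pre-computed estimates on a linear scale, which
#'     is how risk ratios, mean differences, etc. enter the package.
#' }
#' A table carrying columns from both schemas is rejected.
#'
#' @param data A data frame in one of the two schemas.
#' @param zero_cell_policy Passed to [log_odds_ratio()] for the counts schema.
#' @return A tibble with columns `label`, `effect`, `se`, `scale_tag`.
#' @export
study_effects <- function(data, zero_cell_policy = c("haldane", "strict")) {
  if (!is.data.frame(data)) {
    abort_data("`data` must be a data frame.")
  }
  counts_cols <- c("events_trt", "total_trt", "events_ctl", "total_ctl")
  has_counts <- any(counts_cols %in% names(data))
  has_effects <- "effect" %in% names(data) || "se" %in% names(data)
  if (has_counts && has_effects) {
    abort_data("Mixed schemas: supply either 2x2 counts or effect/se columns, not both.")
  }
  if (has_counts) {
    missing_cols <- setdiff(counts_cols, names(data))
    if (length(missing_cols) > 0) {
      abort_data(sprintf(
        "Counts schema is missing column(s): %s.",
        paste(missing_cols, collapse = ", ")
      ))
    }
    for (col in counts_cols) check_numeric_column(data, col)
    return(log_odds_ratio(
      data$events_trt, data$total_trt, data$events_ctl, data$total_ctl,
      label = data$label %||% NULL,
      zero_cell_policy = zero_cell_policy
    ))
  }
  if (has_effects) {
    missing_cols <- setdiff(c("effect", "se"), names(data))
    if (length(missing_cols) > 0) {
      abort_data(sprintf(
        "Effects schema is missing column(s): %s.",
        paste(missing_cols, collapse = ", ")
      ))
    }
    check_numeric_column(data, "effect")
    check_numeric_column(data, "se")
    bad_se <- which(data$se <= 0)
    if (length(bad_se) > 0) {
      abort_data(sprintf(
        "Standard error must be positive: se = %g in row %d.",
        data$se[bad_se[1]], bad_se[1]
      ))
    }
    return(as_study_records(data))
  }
  abort_data(paste(
    "Unrecognized study-table schema: expected columns",
    "{label, events_trt, total_trt, events_ctl, total_ctl} or {label, effect, se}."
  ))
}

check_numeric_column <- function(data, col) {
  x <- data[[col]]
  if (!is.numeric(x)) {
    coerced <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(coerced) & !is.na(x))
    if (length(bad) > 0) {
      abort_data(sprintf(
        "Column `%s` is not numeric: value '%s' in row %d.",
        col, as.character(x[bad[1]]), bad[1]
      ))
    }
    x <- coerced
  }
  bad_na <- which(is.na(x))
  if (length(bad_na) > 0) {
    abort_data(sprintf("Column `%s` has a missing value in row %d.", col, bad_na[1]))
  }
  invisible(x)
}

#' Read a study table from CSV
#'
#' Reads a UTF-8, comma-delimited study table (header row required) in
#' either schema accepted by [study_effects()] and returns study records
#' in file order.
#'
#' @param path Path to the CSV file.
#' @param format_hint `"auto"` (detect from the header), `"counts"`, or
#'   `"effects"`; a hint that contradicts the header is an error.
#' @param zero_cell_policy Passed to [log_odds_ratio()].
#' @return A tibble of study records (see [study_effects()]).
#' @export
read_study_table <- function(path, format_hint = c("auto", "counts", "effects"),
                             zero_cell_policy = c("haldane", "strict")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) {
    abort_data(sprintf("Study table not found: '%s'.", path))
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts_cols <- c("events_trt", "total_trt", "events_ctl", "total_ctl")
  if (format_hint == "counts" && !all(counts_cols %in% names(data))) {
    abort_data("format_hint = \"counts\" but the counts columns are not all present.")
  }
  if (format_hint == "effects" && !all(c("effect", "se") %in% names(data))) {
    abort_data("format_hint = \"effects\" but `effect`/`se` columns are not present.")
  }
  study_effects(data, zero_cell_policy = zero_cell_policy)
}

#' Write study records to CSV
#'
#' Writes the effects schema (`label`, `effect`, `se`, `scale_tag`) so that
#' `read_study_table()` round-trips the records.
#'
#' @param studies A data frame of study records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  studies <- as_study_records(studies)
  readr::write_csv(studies, path, progress = FALSE)
  invisible(path)
}
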