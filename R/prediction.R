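#' t-based prediction interval for the true effect of a new study
#'
#' Under the random-effects model the true effect of a new (or randomly
#' chosen) study is itself a draw from the effect distribution; the
#' prediction interval is the region expected to contain that true effect
#' with probability `level`:
#' \deqn{\hat\theta \pm t_{1-\alpha/2;\,k-2}\sqrt{\hat\tau^2 + \widehat{SE}(\hat\theta)^2}.}
#' The t quantile on \eqn{k - 2} degrees of freedom (rather than a normal
#' quantile) reflects the extra uncertainty from estimating the
#' between-study variation, so at least three studies are required. The
#' interval describes heterogeneity; it carries no information about the
#' statistical significance of the pooled effect, which is judged from the
#' confidence interval only (accordingly, no p-value is attached).
#'
#' @param pooled Pooled effect estimate on the analysis scale.
#' @param se_pooled Its standard error (positive).
#' @param tau2 Between-study variance (non-negative).
#' @param k Number of studies (at least 3, so that df = k - 2 >= 1).
#' @param level Two-sided coverage level, default 0.95.
#' @param scale_tag `"linear"` or `"log_ratio"`; only affects display.
#' @return A `prediction_interval` object with elements `lower`, `upper`,
#'   `level`, `df`, `tau2`, `se_pooled`, `center`, `scale_tag`.
#' @examples
#' prediction_interval(pooled = 0, se_pooled = 0.25, tau2 = 0.25, k = 5)
#' @export
prediction_interval <- function(pooled, se_pooled, tau2, k, level = 0.95,
                                scale_tag = c("linear", "log_ratio")) {
  scale_tag <- match.arg(scale_tag)
  check_level(level)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 3) {
    abort_data("The prediction interval needs k >= 3 studies: its t quantile uses df = k - 2 >= 1.")
  }
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 < 0) {
    abort_data("`tau2` must be a single non-negative number.")
  }
  if (!is.numeric(se_pooled) || length(se_pooled) != 1L ||
      !is.finite(se_pooled) || se_pooled <= 0) {
    abort_data("`se_pooled` must be a single positive number.")
  }
  if (!is.numeric(pooled) || length(pooled) != 1L || !is.finite(pooled)) {
    abort_data("`pooled` must be a single finite number.")
  }
  df <- as.integer(k) - 2L
  half_width <- t_quantile(level, df) * sqrt(tau2 + se_pooled^2)
  structure(
    list(
      lower = pooled - half_width, upper = pooled + half_width,
      level = level, df = df, tau2 = tau2, se_pooled = se_pooled,
      center = pooled, scale_tag = scale_tag
    ),
    class = "prediction_interval"
  )
}

#' Back-derive a standard error from a Wald confidence interval
#'
#' Published meta-analyses report the pooled effect and its confidence
#' interval but rarely the standard error. For a symmetric Wald interval
#' on the analysis (e.g. log) scale,
#' \eqn{se = (upper - lower) / (2 z_{1-\alpha/2})}.
#'
#' @param lower,upper Interval bounds on the analysis scale (`upper > lower`).
#' @param level The level the interval was reported at, default 0.95.
#' @return The implied standard error.
#' @examples
#' se_from_ci(-1.96, 1.96)  # 1
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  check_level(level)
  if (!is.numeric(lower) || !is.numeric(upper) || !is.finite(lower) ||
      !is.finite(upper) || upper <= lower) {
    abort_data("`upper` must be strictly greater than `lower` (both finite).")
  }
  (upper - lower) / (2 * z_quantile(level))
}

#' Prediction interval from a published ratio-scale summary
#'
#' Computes the t-based prediction interval directly from the numbers a
#' published random-effects meta-analysis prints: the pooled ratio (odds
#' ratio, risk ratio, ...), its confidence interval, the between-study
#' standard deviation \eqn{\hat\tau}, and the number of studies. Inputs
#' are log-transformed, the pooled standard error is back-derived from the
#' interval via [se_from_ci()], and [prediction_interval()] is applied;
#' the result stays on the log scale (`scale_tag = "log_ratio"`) and is
#' exponentiated for display, e.g. by [pi_bounds_ratio()].
#'
#' @param pooled_ratio Pooled effect on the ratio scale (positive).
#' @param ci_ratio Length-2 numeric: the reported confidence bounds on the
#'   ratio scale (positive, increasing).
#' @param tau Between-study standard deviation \eqn{\hat\tau} (non-negative);
#'   squared internally.
#' @param k Number of studies (at least 3).
#' @param level Coverage level of both the reported interval and the
#'   prediction interval, default 0.95.
#' @return A `prediction_interval` on the log scale.
#' @examples
#' pi_from_summary(0.34, c(0.22, 0.53), tau = 0.4, k = 8)
#' @export
pi_from_summary <- function(pooled_ratio, ci_ratio, tau, k, level = 0.95) {
  if (!is.numeric(pooled_ratio) || length(pooled_ratio) != 1L ||
      !is.finite(pooled_ratio) || pooled_ratio <= 0) {
    abort_data("`pooled_ratio` must be a single positive number.")
  }
  if (!is.numeric(ci_ratio) || length(ci_ratio) != 2L ||
      any(!is.finite(ci_ratio)) || any(ci_ratio <= 0)) {
    abort_data("`ci_ratio` must be two positive numbers (lower, upper).")
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    abort_data("`tau` must be a single non-negative number.")
  }
  se <- se_from_ci(log(ci_ratio[1]), log(ci_ratio[2]), level = level)
  prediction_interval(
    pooled = log(pooled_ratio), se_pooled = se, tau2 = tau^2, k = k,
    level = level, scale_tag = "log_ratio"
  )
}

#' Prediction interval from a fitted pooling result
#'
#' Convenience wrapper applying [prediction_interval()] to a
#' random-effects [pool_random()] fit, carrying over the estimate, its
#' standard error, the between-study variance, and the scale tag.
#'
#' @param pool A `pool_result` from [pool_random()].
#' @param level Coverage level; defaults to the pooling level.
#' @return A `prediction_interval`.
#' @export
pi_from_pool <- function(pool, level = NULL) {
  stopifnot(inherits(pool, "pool_result"))
  if (pool$model != "random") {
    abort_config("The prediction interval belongs to the random-effects model; fit with pool_random().")
  }
  scale_tag <- if (all(pool$studies$scale_tag == "log_ratio")) "log_ratio" else "linear"
  prediction_interval(
    pooled = pool$pooled, se_pooled = pool$se_pooled, tau2 = pool$tau2,
    k = pool$k, level = level %||% pool$level, scale_tag = scale_tag
  )
}

#' Display bounds of a ratio-scale prediction interval
#'
#' Exponentiates a log-scale interval and rounds for presentation
#' (2 decimal places by default, the convention for ratio measures).
#'
#' @param pi A `prediction_interval`.
#' @param digits Decimal places, default 2.
#' @return Named numeric vector `c(lower, upper)` on the ratio scale.
#' @export
pi_bounds_ratio <- function(pi, digits = 2) {
  stopifnot(inherits(pi, "prediction_interval"))
  if (pi$scale_tag != "log_ratio") {
    abort_data("`pi` is not on the log-ratio scale.")
  }
  round(c(lower = exp(pi$lower), upper = exp(pi$upper)), digits)
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf(
    "%g%% prediction interval (t on %d df, tau^2 = %.4g)\n",
    100 * x$level, x$df, x$tau2
  ))
  if (x$scale_tag == "log_ratio") {
    cat(sprintf(
      "  ratio scale: [%.2f, %.2f]   (log scale: [%.4f, %.4f])\n",
      exp(x$lower), exp(x$upper), x$lower, x$upper
    ))
  } else {
    cat(sprintf("  [%.4f, %.4f]\n", x$lower, x$upper))
  }
  invisible(x)
}

#' @rdname glance.prediction_interval
#' @param x A `prediction_interval`.
#' @param ... Unused.
#' @method tidy prediction_interval
#' @export
tidy.prediction_interval <- function(x, ...) glance.prediction_interval(x, ...)

#' One-row summary of a prediction interval
#'
#' @param x A `prediction_interval`.
#' @param ... Unused.
#' @return A one-row tibble with the bounds, level, degrees of freedom, and
#'   the variance components the interval was built from.
#' @method glance prediction_interval
#' @export
glance.prediction_interval <- function(x, ...) {
  tibble::tibble(
    lower = x$lower, upper = x$upper, level = x$level, df = x$df,
    tau2 = x$tau2, se_pooled = x$se_pooled, center = x$center,
    scale_tag = x$scale_tag
  )
}

prediction_interval_json <- function(x) {
  list(
    lower = x$lower, upper = x$upper, level = x$level, df = x$df,
    tau2 = x$tau2, se_pooled = x$se_pooled, center = x$center,
    scale_tag = x$scale_tag
  )
}
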