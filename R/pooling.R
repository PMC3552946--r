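#' Fixed-effect inverse-variance pooling
#'
#' Pools study effects under the fixed-effect model, which assumes a single
#' true effect underlies all studies so that estimates differ only by
#' sampling error. Weights are the inverse within-study variances
#' \eqn{w_i = 1/se_i^2}; the pooled estimate is \eqn{\sum w_i y_i / \sum w_i}
#' with standard error \eqn{\sqrt{1/\sum w_i}} and a Wald confidence
#' interval on the normal quantile.
#'
#' @param studies Data frame of study records with columns `effect` and `se`
#'   (and optionally `label`), e.g. from [study_effects()].
#' @param level Two-sided confidence level, default 0.95.
#' @return A `pool_result` object; see [tidy.pool_result()] and
#'   [glance.pool_result()] for tidy accessors.
#' @examples
#' studies <- tibble::tibble(effect = c(0, 1), se = c(0.5, 0.5))
#' pool_fixed(studies)
#' @export
pool_fixed <- function(studies, level = 0.95) {
  studies <- as_study_records(studies)
  check_level(level)
  k <- nrow(studies)
  if (k < 1) abort_data("At least one study is required for pooling.")
  w <- 1 / studies$se^2
  pooled <- sum(w * studies$effect) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  z <- z_quantile(level)
  q <- if (k >= 2) cochran_q(studies) else list(q_stat = NA_real_, q_df = 0L)
  i2 <- if (k >= 2) i_squared(q$q_stat, q$q_df) else NA_real_
  new_pool_result(
    model = "fixed", k = k, pooled = pooled, se_pooled = se_pooled,
    ci = c(lower = pooled - z * se_pooled, upper = pooled + z * se_pooled),
    level = level, q_stat = q$q_stat, q_df = q$q_df, tau2 = 0, i2 = i2,
    weights = w / sum(w), studies = studies
  )
}

#' Cochran's Q statistic
#'
#' The weighted sum of squared deviations of study effects from the
#' fixed-effect pooled estimate, \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2}
#' with \eqn{w_i = 1/se_i^2}, on \eqn{k - 1} degrees of freedom. Under
#' homogeneity Q has approximately a chi-squared distribution.
#'
#' @inheritParams pool_fixed
#' @return A list with elements `q_stat` and `q_df`.
#' @export
cochran_q <- function(studies) {
  studies <- as_study_records(studies)
  k <- nrow(studies)
  if (k < 2) abort_data("Cochran's Q requires at least two studies.")
  w <- 1 / studies$se^2
  ybar <- sum(w * studies$effect) / sum(w)
  list(q_stat = sum(w * (studies$effect - ybar)^2), q_df = k - 1L)
}

#' DerSimonian-Laird between-study variance
#'
#' The moment estimator of the between-study variance
#' \deqn{\hat\tau^2 = \max\!\left(0,\;
#'   \frac{Q - (k - 1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' with fixed-effect weights \eqn{w_i = 1/se_i^2}. Truncation at zero is
#' applied, as is standard for this estimator.
#'
#' @inheritParams pool_fixed
#' @return The estimated between-study variance (a single non-negative number).
#' @export
tau2_dersimonian_laird <- function(studies) {
  studies <- as_study_records(studies)
  k <- nrow(studies)
  if (k < 2) abort_data("The DerSimonian-Laird estimator requires at least two studies.")
  w <- 1 / studies$se^2
  q <- cochran_q(studies)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q$q_stat - (k - 1)) / denom)
}

#' I-squared heterogeneity
#'
#' The proportion of total variability in study effects attributable to
#' between-study heterogeneity rather than sampling error, computed from
#' Cochran's Q as \eqn{I^2 = \max(0, (Q - df)/Q)}; 0 when Q = 0.
#'
#' @param q_stat Cochran's Q statistic (non-negative).
#' @param q_df Its degrees of freedom, k - 1 (at least 1).
#' @return A proportion in \[0, 1\].
#' @export
i_squared <- function(q_stat, q_df) {
  if (!is.numeric(q_df) || q_df < 1) {
    abort_data("`q_df` must be at least 1.")
  }
  if (!is.numeric(q_stat) || !is.finite(q_stat) || q_stat < 0) {
    abort_data("`q_stat` must be a non-negative number.")
  }
  if (q_stat == 0) return(0)
  max(0, (q_stat - q_df) / q_stat)
}

#' Random-effects inverse-variance pooling
#'
#' Pools study effects under the random-effects model, in which each
#' study's true effect is drawn from a normal distribution with mean
#' \eqn{\theta} and between-study variance \eqn{\tau^2}; the pooled
#' estimate targets \eqn{\theta}, the mean of the effect distribution.
#' Weights are \eqn{w_i^* = 1/(se_i^2 + \hat\tau^2)} with \eqn{\hat\tau^2}
#' from [tau2_dersimonian_laird()] unless overridden. With
#' \eqn{\hat\tau^2 = 0} the result coincides with [pool_fixed()]: the
#' fixed-effect model is the special case of no between-study variation.
#'
#' @inheritParams pool_fixed
#' @param tau2_override Optional non-negative between-study variance to use
#'   instead of the DerSimonian-Laird estimate (e.g. to reproduce a
#'   published analysis).
#' @return A `pool_result` object.
#' @examples
#' studies <- tibble::tibble(effect = c(0, 1), se = c(0.5, 0.5))
#' pool_random(studies)
#' @export
pool_random <- function(studies, level = 0.95, tau2_override = NULL) {
  studies <- as_study_records(studies)
  check_level(level)
  k <- nrow(studies)
  if (!is.null(tau2_override)) {
    if (!is.numeric(tau2_override) || length(tau2_override) != 1L ||
        !is.finite(tau2_override) || tau2_override < 0) {
      abort_data("`tau2_override` must be a single non-negative number.")
    }
    if (k < 1) abort_data("At least one study is required for pooling.")
    tau2 <- tau2_override
  } else {
    if (k < 2) {
      abort_data("Random-effects pooling requires at least two studies (or a `tau2_override`).")
    }
    tau2 <- tau2_dersimonian_laird(studies)
  }
  w <- 1 / (studies$se^2 + tau2)
  pooled <- sum(w * studies$effect) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  z <- z_quantile(level)
  q <- if (k >= 2) cochran_q(studies) else list(q_stat = NA_real_, q_df = 0L)
  i2 <- if (k >= 2) i_squared(q$q_stat, q$q_df) else NA_real_
  new_pool_result(
    model = "random", k = k, pooled = pooled, se_pooled = se_pooled,
    ci = c(lower = pooled - z * se_pooled, upper = pooled + z * se_pooled),
    level = level, q_stat = q$q_stat, q_df = q$q_df, tau2 = tau2, i2 = i2,
    weights = w / sum(w), studies = studies
  )
}

new_pool_result <- function(model, k, pooled, se_pooled, ci, level,
                            q_stat, q_df, tau2, i2, weights, studies) {
  structure(
    list(
      model = model, k = k, pooled = pooled, se_pooled = se_pooled,
      ci = ci, level = level, q_stat = q_stat, q_df = q_df,
      tau2 = tau2, i2 = i2, weights = weights, studies = studies
    ),
    class = "pool_result"
  )
}

#' @export
print.pool_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "%s-effect%s meta-analysis of %d studies\n",
    if (x$model == "fixed") "Fixed" else "Random",
    if (x$model == "random") "s" else "", x$k
  ))
  cat(sprintf(
    "  pooled = %.*f (SE %.*f), %g%% CI [%.*f, %.*f]\n",
    digits, x$pooled, digits, x$se_pooled, 100 * x$level,
    digits, x$ci[["lower"]], digits, x$ci[["upper"]]
  ))
  if (!is.na(x$q_stat)) {
    cat(sprintf(
      "  Q = %.*f (df = %d), tau^2 = %.*f, I^2 = %.1f%%\n",
      digits, x$q_stat, x$q_df, digits, x$tau2, 100 * x$i2
    ))
  }
  invisible(x)
}

#' Tidy a pooled meta-analysis
#'
#' @param x A `pool_result`.
#' @param ... Unused.
#' @return One row per study: `label`, `effect`, `se`, study-level
#'   confidence bounds at the pooling level, and the normalized weight.
#' @method tidy pool_result
#' @export
tidy.pool_result <- function(x, ...) {
  z <- z_quantile(x$level)
  tibble::tibble(
    label = x$studies$label,
    effect = x$studies$effect,
    se = x$studies$se,
    ci_lower = x$studies$effect - z * x$studies$se,
    ci_upper = x$studies$effect + z * x$studies$se,
    weight = x$weights
  )
}

#' One-row summary of a pooled meta-analysis
#'
#' @param x A `pool_result`.
#' @param ... Unused.
#' @return A one-row tibble: model, k, pooled estimate and SE, confidence
#'   bounds, level, Q, its df, tau-squared, and I-squared.
#' @method glance pool_result
#' @export
glance.pool_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k, pooled = x$pooled, se_pooled = x$se_pooled,
    ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
    level = x$level, q_stat = x$q_stat, q_df = x$q_df,
    tau2 = x$tau2, i2 = x$i2
  )
}

# Flat JSON-ready representation consumed by the report and the CLI.
pool_result_json <- function(x) {
  list(
    model = x$model, k = x$k, pooled = x$pooled, se = x$se_pooled,
    ci_lower = unname(x$ci[["lower"]]), ci_upper = unname(x$ci[["upper"]]),
    level = x$level, q = x$q_stat, q_df = x$q_df, tau2 = x$tau2, i2 = x$i2,
    weights = unname(x$weights)
  )
}
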