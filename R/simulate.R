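#' Within-study standard-error samplers
#'
#' Specify how within-study standard errors are drawn in simulated
#' meta-analyses: uniformly on \[`lo`, `hi`\] (the default model, since
#' real meta-analyses mix studies of varying size) or fixed at a constant.
#'
#' @param lo,hi Positive bounds, `lo <= hi`.
#' @return An `se_sampler` specification.
#' @export
se_uniform <- function(lo = 0.1, hi = 0.5) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi < lo) {
    abort_config("`se_uniform` needs 0 < lo <= hi.")
  }
  structure(list(dist = "uniform", lo = lo, hi = hi), class = "se_sampler")
}

#' @rdname se_uniform
#' @param value Positive constant standard error.
#' @export
se_fixed <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    abort_config("`se_fixed` needs a single positive value.")
  }
  structure(list(dist = "fixed", value = value), class = "se_sampler")
}

draw_se <- function(sampler, k) {
  switch(sampler$dist,
    uniform = runif(k, sampler$lo, sampler$hi),
    fixed = rep(sampler$value, k),
    abort_config(sprintf("Unknown se_sampler distribution '%s'.", sampler$dist))
  )
}

#' Configuration for random-effects simulations
#'
#' Bundles the parameters of the two-level normal hierarchy: each study's
#' true effect is drawn as \eqn{\theta_i \sim N(\theta, \tau^2)} and its
#' estimate as \eqn{y_i \sim N(\theta_i, se_i^2)}, with within-study
#' standard errors from `se_sampler`.
#'
#' @param k Number of studies per meta-analysis (>= 3).
#' @param theta True mean effect.
#' @param tau2 True between-study variance (>= 0).
#' @param se_sampler An [se_uniform()] / [se_fixed()] specification.
#' @param n_reps Number of simulated meta-analyses for experiments (>= 1).
#' @param level Interval level, default 0.95.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(k, theta = 0, tau2 = 0, se_sampler = se_uniform(),
                       n_reps = 1000, level = 0.95, seed = 1) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 3) {
    abort_config("`k` must be an integer >= 3.")
  }
  if (!is.numeric(tau2) || tau2 < 0 || !is.finite(tau2)) {
    abort_config("`tau2` must be non-negative.")
  }
  if (!is.numeric(theta) || !is.finite(theta)) {
    abort_config("`theta` must be finite.")
  }
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    abort_config("`n_reps` must be a positive integer.")
  }
  if (!inherits(se_sampler, "se_sampler")) {
    abort_config("`se_sampler` must be built with se_uniform() or se_fixed().")
  }
  check_level(level)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    abort_config("`seed` must be a single integer.")
  }
  structure(
    list(k = as.integer(k), theta = theta, tau2 = tau2,
         se_sampler = se_sampler, n_reps = as.integer(n_reps),
         level = level, seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_meta <- function(config) {
  se <- draw_se(config$se_sampler, config$k)
  theta_i <- rnorm(config$k, config$theta, sqrt(config$tau2))
  y <- rnorm(config$k, theta_i, se)
  list(se = se, theta_i = theta_i, y = y)
}

#' Simulate one meta-analysis under the random-effects hierarchy
#'
#' Draws `k` study records on the linear scale: within-study standard
#' errors from the configured sampler, true effects from
#' \eqn{N(\theta, \tau^2)}, and observed effects from
#' \eqn{N(\theta_i, se_i^2)}. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble of study records (`label`, `effect`, `se`,
#'   `scale_tag = "linear"`) with the true per-study effects in a
#'   `true_effect` column.
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  d <- draw_meta(config)
  tibble::tibble(
    label = paste("Study", seq_len(config$k)),
    effect = d$y, se = d$se, scale_tag = "linear", true_effect = d$theta_i
  )
}

# Minimal DL fit used inside tight simulation loops; numerically identical
# to pool_random() + pi_from_pool() (asserted by tests) but without tibble
# or validation overhead.
pool_dl_fast <- function(y, se, level) {
  w <- 1 / se^2
  sw <- sum(w)
  ybar <- sum(w * y) / sw
  q <- sum(w * (y - ybar)^2)
  k <- length(y)
  tau2 <- max(0, (q - (k - 1)) / (sw - sum(w^2) / sw))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se_pooled <- sqrt(1 / sum(ws))
  list(pooled = pooled, se_pooled = se_pooled, tau2 = tau2)
}

#' Monte-Carlo coverage experiment for the prediction interval
#'
#' Repeats, `n_reps` times: simulate a meta-analysis from the hierarchy,
#' fit the random-effects model with DerSimonian-Laird, form the t-based
#' prediction interval and the pooled-effect confidence interval, draw one
#' new true effect \eqn{\theta_{new} \sim N(\theta, \tau^2)}, and record
#' whether the prediction interval contains \eqn{\theta_{new}} and whether
#' the confidence interval contains \eqn{\theta}. The defining property of
#' the prediction interval is that the first proportion is approximately
#' the nominal level; a z-quantile variant of the interval is tracked
#' alongside to show that it under-covers for small `k`.
#'
#' Per-replicate random substreams are derived deterministically from
#' `config$seed`, so identical configurations give identical results.
#'
#' @param config A [sim_config()].
#' @return A `sim_result` with coverage proportions
#'   (`pi_coverage_new_effect`, `pi_coverage_new_effect_z`,
#'   `ci_coverage_theta`), estimator means (`mean_tau2_hat`,
#'   `mean_pooled`), and Monte-Carlo standard errors `mc_se`.
#' @export
coverage_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  t_q <- t_quantile(config$level, config$k - 2L)
  z_q <- z_quantile(config$level)
  hit_t <- hit_z <- hit_ci <- logical(config$n_reps)
  tau2_hat <- pooled_hat <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    d <- draw_meta(config)
    theta_new <- rnorm(1, config$theta, sqrt(config$tau2))
    fit <- pool_dl_fast(d$y, d$se, config$level)
    half_pi <- sqrt(fit$tau2 + fit$se_pooled^2)
    hit_t[r] <- abs(theta_new - fit$pooled) <= t_q * half_pi
    hit_z[r] <- abs(theta_new - fit$pooled) <= z_q * half_pi
    hit_ci[r] <- abs(config$theta - fit$pooled) <= z_q * fit$se_pooled
    tau2_hat[r] <- fit$tau2
    pooled_hat[r] <- fit$pooled
  }
  prop <- function(x) mean(x)
  mc <- function(p) sqrt(p * (1 - p) / config$n_reps)
  p_t <- prop(hit_t); p_z <- prop(hit_z); p_ci <- prop(hit_ci)
  structure(
    list(
      pi_coverage_new_effect = p_t,
      pi_coverage_new_effect_z = p_z,
      ci_coverage_theta = p_ci,
      mean_tau2_hat = mean(tau2_hat),
      mean_pooled = mean(pooled_hat),
      mc_se = c(
        pi_coverage_new_effect = mc(p_t),
        pi_coverage_new_effect_z = mc(p_z),
        ci_coverage_theta = mc(p_ci)
      ),
      config = config
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Coverage experiment: k = %d, theta = %g, tau2 = %g, %d reps, level %g\n",
    cfg$k, cfg$theta, cfg$tau2, cfg$n_reps, cfg$level
  ))
  cat(sprintf(
    "  PI coverage of theta_new: %.4f (t) / %.4f (z)  [mc se %.4f]\n",
    x$pi_coverage_new_effect, x$pi_coverage_new_effect_z,
    x$mc_se[["pi_coverage_new_effect"]]
  ))
  cat(sprintf(
    "  CI coverage of theta: %.4f;  mean tau2_hat = %.4f; mean pooled = %.4f\n",
    x$ci_coverage_theta, x$mean_tau2_hat, x$mean_pooled
  ))
  invisible(x)
}

#' One-row summary of a coverage experiment
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A one-row tibble of the coverage proportions, estimator means,
#'   and Monte-Carlo standard errors.
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  tibble::tibble(
    k = x$config$k, theta = x$config$theta, tau2 = x$config$tau2,
    n_reps = x$config$n_reps, level = x$config$level,
    pi_coverage_new_effect = x$pi_coverage_new_effect,
    pi_coverage_new_effect_z = x$pi_coverage_new_effect_z,
    ci_coverage_theta = x$ci_coverage_theta,
    mean_tau2_hat = x$mean_tau2_hat,
    mean_pooled = x$mean_pooled,
    mc_se_pi = x$mc_se[["pi_coverage_new_effect"]]
  )
}

sim_result_json <- function(x) {
  list(
    pi_coverage_new_effect = x$pi_coverage_new_effect,
    pi_coverage_new_effect_z = x$pi_coverage_new_effect_z,
    ci_coverage_theta = x$ci_coverage_theta,
    mean_tau2_hat = x$mean_tau2_hat,
    mean_pooled = x$mean_pooled,
    mc_se = as.list(x$mc_se),
    config = list(
      k = x$config$k, theta = x$config$theta, tau2 = x$config$tau2,
      se_sampler = unclass(x$config$se_sampler), n_reps = x$config$n_reps,
      level = x$config$level, seed = x$config$seed
    )
  )
}
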