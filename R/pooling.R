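# Inverse-variance fixed-effect and DerSimonian-Laird random-effects
# pooling of per-study log odds ratios, with Cochran Q, I-squared and
# tau-squared heterogeneity statistics.

#' Cochran's Q test of homogeneity
#'
#' Weighted sum of squared deviations of study effects from the
#' fixed-effect (inverse-variance weighted) mean,
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2} with \eqn{w_i = 1/se_i^2},
#' referred to a chi-square distribution with k-1 degrees of freedom.
#' A single study gives Q = 0, p = 1 by convention.
#'
#' @param estimates Data frame with columns `log_or` and `se` (one row per
#'   study), e.g. from [estimate_effects()].
#' @return A list with `q`, `df`, and `p_q`.
#' @examples
#' est <- data.frame(log_or = c(0, 1), se = c(0.2, 0.2))
#' cochran_q(est)   # q = 12.5 on 1 df
#' @export
cochran_q <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "cochran_q")
  y <- estimates$log_or; w <- 1 / estimates$se^2
  k <- length(y)
  if (k == 1) return(list(q = 0, df = 0L, p_q = 1))
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  list(q = q, df = k - 1L,
       p_q = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' The I-squared inconsistency index
#'
#' Percentage of total variability in the study effects attributable to
#' between-study heterogeneity rather than chance:
#' \eqn{I^2 = 100 \cdot \max(0, (Q - df)/Q)}, defined as 0 when Q = 0.
#'
#' @param q Cochran Q statistic (non-negative).
#' @param df Its degrees of freedom (k - 1).
#' @return I-squared on the 0-100 percent scale.
#' @examples
#' i_squared(12.5, 1)   # 92%
#' @export
i_squared <- function(q, df) {
  stopifnot(q >= 0, df >= 0)
  if (q == 0) return(0)
  100 * max(0, (q - df) / q)
}

make_pooled <- function(estimates, weights, tau2, method, model) {
  y <- estimates$log_or
  w <- weights
  pooled <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  qres <- cochran_q(estimates)
  wn <- w / sum(w)
  names(wn) <- study_ids_of(estimates)
  structure(list(model = model, method = method, k = nrow(estimates),
                 pooled_log_or = pooled, pooled_or = exp(pooled),
                 pooled_se = se,
                 ci95 = exp(pooled + c(-1, 1) * Z95 * se),
                 z = z, p_z = 2 * stats::pnorm(-abs(z)),
                 q = qres$q, p_q = qres$p_q,
                 i2 = i_squared(qres$q, qres$df),
                 tau2 = tau2, weights = wn),
            class = "pooled_result")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools per-study log odds ratios with weights \eqn{w_i = 1/se_i^2}. The
#' pooled standard error is \eqn{1/\sqrt{\sum w_i}}; significance is a
#' two-sided Z-test of the pooled log OR against zero. Heterogeneity
#' statistics (Q, I-squared) are carried in the result.
#'
#' @param estimates Data frame with columns `log_or` and `se`; an optional
#'   `study_id` column names the weights, an optional `model` column labels
#'   the result.
#' @return An object of class `"pooled_result"`; see [pool_random_dl()] for
#'   the fields.
#' @export
pool_fixed <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "pool_fixed")
  make_pooled(estimates, 1 / estimates$se^2, tau2 = 0, method = "fixed",
              model = estimates$model[1] %||% NA_character_)
}

#' Estimate the between-study variance by DerSimonian-Laird moments
#'
#' \eqn{\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}}
#' with fixed-effect weights \eqn{w_i = 1/se_i^2}.
#'
#' @inheritParams pool_fixed
#' @return Non-negative tau-squared; 0 when k = 1.
#' @export
tau2_dl <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "tau2_dl")
  k <- nrow(estimates)
  if (k == 1) return(0)
  w <- 1 / estimates$se^2
  q <- cochran_q(estimates)$q
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Random-effects pooling with the method-of-moments between-study variance
#' [tau2_dl()]: study weights are \eqn{w_i^* = 1/(se_i^2 + \hat\tau^2)}, and
#' pooled estimate, 95% CI (normal quantile on the log scale), Z and p
#' follow as in [pool_fixed()] with the starred weights. When the Q
#' statistic does not exceed its degrees of freedom, \eqn{\hat\tau^2}
#' truncates to zero and the result coincides with the fixed-effect model
#' exactly. A single study is returned as its own estimate with
#' \eqn{\hat\tau^2 = 0}.
#'
#' @inheritParams pool_fixed
#' @return An object of class `"pooled_result"`: a list with `model`,
#'   `method` (`"fixed"` or `"random"`), `k`, `pooled_log_or`, `pooled_or`,
#'   `pooled_se`, `ci95` (OR scale), `z`, `p_z`, `q`, `p_q`, `i2` (percent),
#'   `tau2`, and normalized `weights` (named by study, summing to 1).
#' @examples
#' est <- data.frame(log_or = c(0, 1), se = c(0.2, 0.2))
#' pool_random_dl(est)   # tau2 = 0.46, pooled log OR = 0.5
#' @export
pool_random_dl <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "pool_random_dl")
  tau2 <- tau2_dl(estimates)
  make_pooled(estimates, 1 / (estimates$se^2 + tau2), tau2 = tau2,
              method = "random", model = estimates$model[1] %||% NA_character_)
}

#' Classify heterogeneity of a pooled result
#'
#' Significance uses the conventional liberal threshold P(Q) < 0.10 (the Q
#' test has low power with few studies); the magnitude bands follow the
#' usual I-squared reading: < 25% none or little, 25-50% moderate
#' (boundaries inclusive), > 50% strong.
#'
#' @param result A `"pooled_result"`.
#' @param p_threshold Significance cut for P(Q).
#' @return A list of class `"heterogeneity_verdict"` with `significant` and
#'   `band` (`"none_or_little"`, `"moderate"`, `"strong"`).
#' @export
classify_heterogeneity <- function(result, p_threshold = 0.10) {
  stopifnot(inherits(result, "pooled_result"))
  band <- if (result$i2 < 25) "none_or_little"
          else if (result$i2 <= 50) "moderate"
          else "strong"
  structure(list(significant = result$p_q < p_threshold, band = band),
            class = "heterogeneity_verdict")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s-effects pool of %d studies%s\n",
              if (x$method == "random") "Random" else "Fixed", x$k,
              if (!is.na(x$model)) paste0(" [", x$model, " model]") else ""))
  cat("  OR (95% CI); P(Z):", format_or_ci(x$pooled_or, x$ci95, x$p_z), "\n")
  cat(sprintf("  heterogeneity: Q = %.3f, P(Q) = %s, I2 = %.0f%%, tau2 = %.4f\n",
              x$q, format_p(x$p_q), x$i2, x$tau2))
  invisible(x)
}

#' @export
print.heterogeneity_verdict <- function(x, ...) {
  cat(sprintf("heterogeneity: %s (%ssignificant at P(Q) threshold)\n",
              gsub("_", " ", x$band), if (x$significant) "" else "not "))
  invisible(x)
}
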