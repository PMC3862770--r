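# Small-study / publication-bias diagnostics: funnel-plot coordinates,
# Egger regression asymmetry, and the Begg-Mazumdar rank correlation.

#' Funnel-plot coordinates
#'
#' One point per study: effect (log OR) against precision (1/se), plus the
#' standardized effect used by Egger regression. The data frame is directly
#' plottable; no drawing is done here.
#'
#' @inheritParams pool_fixed
#' @return Data frame with columns `study_id`, `log_or`, `se`, `precision`,
#'   `standardized_effect`.
#' @export
funnel_data <- function(estimates) {
  if (nrow(estimates) == 0)
    return(data.frame(study_id = character(0), log_or = numeric(0),
                      se = numeric(0), precision = numeric(0),
                      standardized_effect = numeric(0)))
  check_estimates(estimates, min_k = 1, caller = "funnel_data")
  data.frame(study_id = study_ids_of(estimates),
             log_or = estimates$log_or,
             se = estimates$se,
             precision = 1 / estimates$se,
             standardized_effect = estimates$log_or / estimates$se,
             stringsAsFactors = FALSE)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect \eqn{y_i/se_i} on the
#' precision \eqn{1/se_i} (the original unweighted formulation). The
#' intercept is the asymmetry statistic: under a symmetric funnel small and
#' large studies scatter around the same underlying effect and the
#' intercept is zero. Significance is a two-sided t-test of the intercept
#' on k - 2 degrees of freedom. A precision-weighted variant (weights
#' \eqn{1/se_i^2} in the same regression) is available behind `weighted`.
#'
#' @inheritParams pool_fixed
#' @param weighted Use the precision-weighted variant instead of plain OLS.
#' @return An object of class `"egger_result"`: `intercept`,
#'   `intercept_se`, `slope`, `t`, `df`, `p`, `weighted`.
#' @export
egger_test <- function(estimates, weighted = FALSE) {
  check_estimates(estimates, min_k = 1, caller = "egger_test")
  k <- nrow(estimates)
  if (k < 3)
    stop("egger_test requires at least 3 studies, got ", k, call. = FALSE)
  x <- 1 / estimates$se
  y <- estimates$log_or / estimates$se
  if (max(x) - min(x) < 1e-12 * max(x))
    stop("egger_test: identical standard errors across studies give a ",
         "singular regression design", call. = FALSE)
  w <- if (weighted) x^2 else rep(1, k)
  sw <- sum(w)
  xbar <- sum(w * x) / sw; ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(w * resid^2) / (k - 2)
  se_int <- sqrt(s2 * (1 / sw + xbar^2 / sxx))
  tval <- intercept / se_int
  structure(list(intercept = intercept, intercept_se = se_int, slope = slope,
                 t = tval, df = k - 2L,
                 p = 2 * stats::pt(-abs(tval), df = k - 2),
                 weighted = weighted),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger%s regression: intercept = %.4f (se %.4f), t = %.3f on %d df, p = %s\n",
              if (x$weighted) " (weighted)" else "", x$intercept,
              x$intercept_se, x$t, x$df, format_p(x$p)))
  invisible(x)
}

# Ties-corrected Kendall tau-b with normal-approximation p (no continuity
# correction), computed from explicit pairwise concordance counts.
kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  tau <- if (denom == 0) 0 else (conc - disc) / denom
  # variance of S = conc - disc under the null, with tie correction
  tie_counts <- function(v) {
    tab <- table(v)
    tab <- tab[tab > 1]
    as.numeric(tab)
  }
  vS <- function() {
    t_x <- tie_counts(x); t_y <- tie_counts(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(t_x * (t_x - 1) * (2 * t_x + 5))
    vu <- sum(t_y * (t_y - 1) * (2 * t_y + 5))
    v1 <- sum(t_x * (t_x - 1)) * sum(t_y * (t_y - 1)) / (2 * n * (n - 1))
    v2 <- sum(t_x * (t_x - 1) * (t_x - 2)) * sum(t_y * (t_y - 1) * (t_y - 2)) /
      (9 * n * (n - 1) * (n - 2))
    (v0 - vt - vu) / 18 + v1 + v2
  }
  S <- conc - disc
  v <- vS()
  z <- if (v > 0) S / sqrt(v) else 0
  list(tau = tau, S = S, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall rank correlation between the standardized study effects
#' (centered at the fixed-effect pooled estimate, with the pooled variance
#' subtracted from each study variance before standardizing) and the study
#' variances. A correlation indicates that smaller (higher-variance)
#' studies show systematically different effects. The p-value uses the
#' ties-corrected normal approximation without continuity correction.
#'
#' @inheritParams pool_fixed
#' @return A list of class `"begg_result"`: `kendall_tau`, `z`, `p`, `k`.
#' @export
begg_test <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "begg_test")
  k <- nrow(estimates)
  if (k < 3)
    stop("begg_test requires at least 3 studies, got ", k, call. = FALSE)
  v <- estimates$se^2
  w <- 1 / v
  ybar <- sum(w * estimates$log_or) / sum(w)
  vstar <- v - 1 / sum(w)
  vstar[vstar <= 0] <- .Machine$double.eps  # guard: dominant single study
  t_i <- (estimates$log_or - ybar) / sqrt(vstar)
  kt <- kendall_tau_b(t_i, v)
  structure(list(kendall_tau = kt$tau, z = kt$z, p = kt$p, k = k),
            class = "begg_result")
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("Begg rank correlation (k = %d): tau = %.4f, z = %.3f, p = %s\n",
              x$k, x$kendall_tau, x$z, format_p(x$p)))
  invisible(x)
}
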