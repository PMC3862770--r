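# Univariate random-effects meta-regression of study log ORs on a
# study-level moderator, with method-of-moments (default) or REML residual
# between-study variance.

MODERATORS <- c("ethnicity", "size", "size_class", "followup_months",
                "mean_age", "pct_male", "year")

encode_moderator <- function(estimates, moderator, size_threshold = 500) {
  x <- switch(moderator,
              ethnicity = {
                e <- estimates$ethnicity
                ifelse(e == "Asian", 1, ifelse(e == "Caucasian", 0, NA))
              },
              size_class = as.numeric(estimates$size >= size_threshold),
              estimates[[moderator]])
  if (is.null(x))
    stop("unknown moderator '", moderator, "'; available: ",
         paste(intersect(c(MODERATORS, names(estimates)), names(estimates)),
               collapse = ", "), call. = FALSE)
  as.numeric(x)
}

# Residual method-of-moments tau2 for design matrix X (generalizes the
# DerSimonian-Laird estimator to the regression case):
#   tau2 = max(0, (QE - (k - p)) / (tr(W) - tr[(X'WX)^{-1} X'W^2X]))
# with W = diag(1/v_i) and QE the weighted residual sum of squares of the
# fixed-effect WLS fit.
tau2_mm_reg <- function(y, v, X) {
  k <- length(y); p <- ncol(X)
  W <- diag(1 / v, k)
  XtW <- t(X) %*% W
  XtWX_inv <- solve(XtW %*% X)
  beta <- XtWX_inv %*% XtW %*% y
  resid <- y - X %*% beta
  QE <- sum((resid^2) / v)
  denom <- sum(1 / v) - sum(diag(XtWX_inv %*% (t(X) %*% diag(1 / v^2, k) %*% X)))
  max(0, (QE - (k - p)) / denom)
}

# Restricted log-likelihood of tau2 for the WLS meta-regression model.
reml_ll <- function(tau2, y, v, X) {
  wi <- 1 / (v + tau2)
  W <- diag(wi, length(y))
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  resid <- y - X %*% beta
  -0.5 * (sum(log(v + tau2)) + log(det(XtWX)) + sum(wi * resid^2))
}

tau2_reml_reg <- function(y, v, X, tol = 1e-10) {
  upper <- max(stats::var(y) * 4, max(v) * 10, 1)
  opt <- stats::optimize(reml_ll, c(0, upper), y = y, v = v, X = X,
                         maximum = TRUE, tol = tol)
  # the maximizer may sit at the boundary; prefer exact zero when flat
  if (reml_ll(0, y, v, X) >= opt$objective) 0 else max(0, opt$maximum)
}

#' Univariate random-effects meta-regression
#'
#' Regresses per-study log odds ratios on one study-level moderator with
#' weights \eqn{1/(se_i^2 + \hat\tau^2_{res})}. The residual between-study
#' variance is estimated by the method of moments (`method = "mm"`, the
#' regression generalization of DerSimonian-Laird; default) or by REML.
#' Moderator encodings: `ethnicity` is Asian = 1 / Caucasian = 0 (other
#' groups dropped with a diagnostic), `size` is total N (continuous),
#' `size_class` is the large/small indicator at `size_threshold`,
#' `followup_months`, `mean_age` (years), `pct_male`, `year` are taken as
#' recorded. Studies with a missing moderator are dropped with a
#' diagnostic. A constant moderator degenerates to the intercept-only
#' model, whose intercept is exactly the DerSimonian-Laird pooled log OR.
#'
#' @inheritParams pool_fixed
#' @param moderator Moderator name (see Details) or any numeric column of
#'   `estimates`.
#' @param method `"mm"` (method of moments, default) or `"reml"`.
#' @param size_threshold Threshold for the `size_class` encoding.
#' @return An object of class `"metareg_fit"`: `moderator`, `beta0`,
#'   `beta1`, `se0`, `se1`, `z1`, `p_beta1`, `tau2_resid`, `k`,
#'   `k_dropped`, `method`. For a degenerate (constant) moderator `beta1`,
#'   `se1`, `p_beta1` are `NA` and `degenerate` is `TRUE`.
#' @examples
#' est <- data.frame(log_or = c(0.1, 0.5, 0.3, 0.8), se = rep(0.2, 4),
#'                   mean_age = c(50, 60, 55, 70))
#' meta_regress(est, "mean_age")
#' @export
meta_regress <- function(estimates, moderator, method = c("mm", "reml"),
                         size_threshold = 500) {
  method <- match.arg(method)
  check_estimates(estimates, min_k = 1, caller = "meta_regress")
  x <- encode_moderator(estimates, moderator, size_threshold)
  keep <- !is.na(x)
  k_dropped <- sum(!keep)
  est <- estimates[keep, , drop = FALSE]
  x <- x[keep]
  k <- nrow(est)
  if (k < 3)
    stop("meta_regress requires >= 3 studies with a non-missing moderator, got ",
         k, call. = FALSE)
  y <- est$log_or; v <- est$se^2

  if (max(x) - min(x) < 1e-12 * max(abs(x), 1)) {
    pooled <- pool_random_dl(est)
    return(structure(list(moderator = moderator, beta0 = pooled$pooled_log_or,
                          beta1 = NA_real_, se0 = pooled$pooled_se,
                          se1 = NA_real_, z1 = NA_real_, p_beta1 = NA_real_,
                          tau2_resid = pooled$tau2, k = k,
                          k_dropped = k_dropped, method = method,
                          degenerate = TRUE),
                     class = "metareg_fit"))
  }

  X <- cbind(1, x)
  tau2 <- if (method == "mm") tau2_mm_reg(y, v, X) else tau2_reml_reg(y, v, X)
  wi <- 1 / (v + tau2)
  W <- diag(wi, k)
  cov_beta <- solve(t(X) %*% W %*% X)
  beta <- as.numeric(cov_beta %*% t(X) %*% W %*% y)
  se <- unname(sqrt(diag(cov_beta)))
  z1 <- beta[2] / se[2]
  structure(list(moderator = moderator, beta0 = beta[1], beta1 = beta[2],
                 se0 = se[1], se1 = se[2], z1 = z1,
                 p_beta1 = 2 * stats::pnorm(-abs(z1)),
                 tau2_resid = tau2, k = k, k_dropped = k_dropped,
                 method = method, degenerate = FALSE),
            class = "metareg_fit")
}

#' @export
print.metareg_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("meta-regression on '%s': constant moderator; intercept-only\n",
                x$moderator))
    cat(sprintf("  beta0 = %.4f (se %.4f), tau2 = %.4f, k = %d\n",
                x$beta0, x$se0, x$tau2_resid, x$k))
  } else {
    cat(sprintf("meta-regression on '%s' (%s tau2), k = %d%s\n", x$moderator,
                x$method, x$k,
                if (x$k_dropped) sprintf(" (%d dropped: missing moderator)",
                                         x$k_dropped) else ""))
    cat(sprintf("  slope  beta1 = %.4f (se %.4f), p = %s\n",
                x$beta1, x$se1, format_p(x$p_beta1)))
    cat(sprintf("  intercept beta0 = %.4f (se %.4f); residual tau2 = %.4f\n",
                x$beta0, x$se0, x$tau2_resid))
  }
  invisible(x)
}
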