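# Independent oracles used to cross-check the package's own statistics.
# These deliberately use different code paths: plain textbook arithmetic,
# stats::lm, stats::cor.test, stats::chisq.test, and (where available)
# metafor.

# Textbook DerSimonian-Laird computation, written as flat arithmetic.
oracle_dl <- function(y, v) {
  w <- 1 / v
  ybar_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar_fe)^2)
  k <- length(y)
  tau2 <- if (k == 1) 0 else
    max(0, (Q - (k - 1)) / (sum(w) - sum(w * w) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(q = Q, tau2 = tau2, mu = mu, se = se,
       i2 = if (Q == 0) 0 else 100 * max(0, (Q - (k - 1)) / Q))
}

# Egger regression via stats::lm on the standardized pairs.
oracle_egger <- function(y, se) {
  # near-exact instances trip summary.lm's perfect-fit warning
  fit <- suppressWarnings(summary(stats::lm(I(y / se) ~ I(1 / se))))
  co <- stats::coef(fit)
  list(intercept = co[1, 1], intercept_se = co[1, 2],
       slope = co[2, 1], t = co[1, 3], p = co[1, 4])
}

# Brute-force Kendall S (concordant minus discordant pairs) by exhaustive
# pair enumeration.
oracle_kendall_S <- function(x, y) {
  S <- 0
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j > i) S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  S
}

# Standardized deviates used by the Begg rank-correlation test.
begg_deviates <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  vstar <- pmax(v - 1 / sum(w), .Machine$double.eps)
  (y - ybar) / sqrt(vstar)
}

# Random small meta-analysis instance on the estimates-table interface.
rand_estimates <- function(k = NULL) {
  if (is.null(k)) k <- sample(2:8, 1)
  data.frame(study_id = sprintf("s%02d", seq_len(k)),
             log_or = stats::rnorm(k, 0.2, 0.6),
             se = stats::runif(k, 0.05, 0.8))
}

# A small genotype cohort with every model estimable (no zero classes).
demo_records <- function(k = 6, seed = 101) {
  simulate_studies(sim_config(k_studies = k, p_D = 0.45, or_true = 1.4,
                              tau2 = 0.02, n_case_range = c(80, 200),
                              n_ctrl_range = c(150, 400), seed = seed))
}
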