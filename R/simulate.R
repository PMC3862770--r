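# Synthetic study-collection generator with known truth, used as the
# fixture factory for the whole pipeline: per-allele odds ratio or_true,
# between-study variance tau2, control genotypes at Hardy-Weinberg
# equilibrium, case genotypes tilted multiplicatively per D allele.

#' Simulation configuration
#'
#' Defaults emulate a published restenosis study collection: 23 datasets,
#' publication years 1993-2012, follow-up within the 3-12 month window,
#' arm sizes spanning the printed range of that cohort (cases 15-513,
#' controls 25-2572), 60-90% male, High/Median quality labels.
#'
#' @param k_studies Number of study datasets (>= 1).
#' @param p_D Control-population D-allele frequency, in (0, 1) exclusive.
#' @param or_true True per-allele odds ratio (> 0).
#' @param tau2 Between-study variance of the study-specific log OR (>= 0).
#' @param n_case_range,n_ctrl_range Integer ranges for per-study arm sizes
#'   (cases and controls drawn uniformly).
#' @param ethnicity_mix Proportion of studies labeled Asian (the rest
#'   Caucasian).
#' @param intervention Intervention label stamped on all studies.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param selection Optional publication-bias rule: a list with
#'   `p_threshold` and `suppress_prob` — a simulated study whose allele-
#'   contrast p-value exceeds `p_threshold` is discarded (and redrawn) with
#'   probability `suppress_prob`, mimicking suppression of null results.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(k_studies = 23, p_D = 0.5, or_true = 1.3, tau2 = 0,
                       n_case_range = c(15, 513), n_ctrl_range = c(25, 2572),
                       ethnicity_mix = 0.5, intervention = "stent",
                       seed = NULL, selection = NULL) {
  stopifnot(k_studies >= 1, or_true > 0, tau2 >= 0,
            length(n_case_range) == 2, n_case_range[1] >= 1,
            n_case_range[1] <= n_case_range[2],
            length(n_ctrl_range) == 2, n_ctrl_range[1] >= 1,
            n_ctrl_range[1] <= n_ctrl_range[2],
            ethnicity_mix >= 0, ethnicity_mix <= 1)
  if (!is.null(p_D) && (p_D <= 0 || p_D >= 1))
    stop("p_D must lie strictly inside (0, 1): a fixed allele gives a ",
         "degenerate genotype distribution", call. = FALSE)
  if (!is.null(selection))
    stopifnot(is.list(selection), selection$p_threshold > 0,
              selection$p_threshold < 1, selection$suppress_prob >= 0,
              selection$suppress_prob <= 1)
  structure(list(k_studies = as.integer(k_studies), p_D = p_D,
                 or_true = or_true, tau2 = tau2,
                 n_case_range = as.integer(n_case_range),
                 n_ctrl_range = as.integer(n_ctrl_range),
                 ethnicity_mix = ethnicity_mix, intervention = intervention,
                 seed = seed, selection = selection),
            class = "sim_config")
}

# genotype probabilities (II, ID, DD) at HWE allele frequency p
hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# uniform integer in [lo, hi]; safe when lo == hi (unlike sample(lo:hi, 1))
runif_int <- function(range) range[1] + sample.int(range[2] - range[1] + 1, 1) - 1

# case probabilities: control probs tilted by exp(theta) per D allele
case_probs <- function(ctrl_probs, theta) {
  tilt <- ctrl_probs * exp(theta * (0:2))
  tilt / sum(tilt)
}

draw_one_study <- function(cfg, i) {
  theta <- stats::rnorm(1, log(cfg$or_true), sqrt(cfg$tau2))
  n_case <- runif_int(cfg$n_case_range)
  n_ctrl <- runif_int(cfg$n_ctrl_range)
  pc <- hwe_probs(cfg$p_D)
  g_ctrl <- as.vector(stats::rmultinom(1, n_ctrl, pc))
  g_case <- as.vector(stats::rmultinom(1, n_case, case_probs(pc, theta)))
  data.frame(study_id = sprintf("sim%03d", i),
             year = sample(1993:2012, 1),
             ethnicity = if (stats::runif(1) < cfg$ethnicity_mix) "Asian" else "Caucasian",
             ethnicity_label = NA, intervention = cfg$intervention,
             followup_months = sample(c(3, 4, 6, 6, 6, 9, 12), 1),
             restenosis_definition = "diameter stenosis >=50%",
             n_case_II = g_case[1], n_case_ID = g_case[2], n_case_DD = g_case[3],
             n_ctrl_II = g_ctrl[1], n_ctrl_ID = g_ctrl[2], n_ctrl_DD = g_ctrl[3],
             a_case_I = 2 * g_case[1] + g_case[2],
             a_case_D = 2 * g_case[3] + g_case[2],
             a_ctrl_I = 2 * g_ctrl[1] + g_ctrl[2],
             a_ctrl_D = 2 * g_ctrl[3] + g_ctrl[2],
             cases_total = n_case, controls_total = n_ctrl,
             mean_age = round(stats::runif(1, 52, 70), 1),
             pct_male = round(stats::runif(1, 60, 90), 1),
             quality = sample(c("High", "Median"), 1),
             ace_inhibitor_stratum = "unstratified",
             stringsAsFactors = FALSE)
}

allele_p_value <- function(row) {
  tab <- continuity_correct(build_contrast(as.list(row), "allele"))
  est <- estimate_effect(tab)
  2 * stats::pnorm(-abs(est$log_or / est$se))
}

#' Simulate a collection of genetic association studies
#'
#' For each study: a study-specific true log OR is drawn from
#' Normal(log `or_true`, `tau2`); control genotypes are multinomial at
#' Hardy-Weinberg proportions for `p_D`; case genotype probabilities are
#' the control probabilities tilted by `exp(theta)` per D allele and
#' renormalized (a logistic-consistent per-allele risk model); counts are
#' drawn at the sampled arm sizes; study metadata are filled from the
#' configured ranges. With a `selection` rule, suppressed studies are
#' redrawn so exactly `k_studies` are returned.
#'
#' @param config A [sim_config()] (or arguments for one via `...`).
#' @param ... Passed to [sim_config()] when `config` is missing.
#' @return A `study_records` data frame, identical in schema to
#'   [load_studies()] output.
#' @examples
#' studies <- simulate_studies(sim_config(k_studies = 5, seed = 42))
#' summarize_cohort(studies)
#' @export
simulate_studies <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) sim_config(...) else config
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rows <- vector("list", cfg$k_studies)
  for (i in seq_len(cfg$k_studies)) {
    attempts <- 0
    repeat {
      row <- draw_one_study(cfg, i)
      attempts <- attempts + 1
      if (is.null(cfg$selection) || attempts >= 1000) break
      p <- allele_p_value(row)
      suppressed <- p > cfg$selection$p_threshold &&
        stats::runif(1) < cfg$selection$suppress_prob
      if (!suppressed) break
    }
    rows[[i]] <- row
  }
  as_study_records(do.call(rbind, rows))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a study collection, runs the allele-contrast
#' random-effects pipeline, and aggregates estimation quality: mean pooled
#' OR, bias and RMSE of the pooled log OR, empirical 95% CI coverage of
#' `or_true`, mean estimated tau2, and the mean Egger intercept and p
#' (where computable).
#'
#' @param config A [sim_config()]; its `seed` seeds replicate r with
#'   `seed + r`.
#' @param n_reps Number of replicates (>= 1).
#' @return A list of class `"recovery_report"` with `per_rep` (data frame,
#'   one row per replicate) and aggregate fields `mean_or`, `bias_log_or`,
#'   `rmse_log_or`, `coverage`, `mean_tau2`, `mean_egger_intercept`,
#'   `mean_egger_p`, `n_reps`, `config`.
#' @export
recovery_experiment <- function(config, n_reps) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  base_seed <- config$seed %||% 1
  per <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- base_seed + r
    studies <- simulate_studies(cfg)
    est <- estimate_effects(studies, "allele")
    pooled <- pool_random_dl(est)
    egger <- tryCatch(egger_test(est), error = function(e) NULL)
    per[[r]] <- data.frame(
      rep = r, pooled_or = pooled$pooled_or,
      pooled_log_or = pooled$pooled_log_or,
      ci_low = pooled$ci95[1], ci_high = pooled$ci95[2],
      covered = pooled$ci95[1] <= config$or_true &
        config$or_true <= pooled$ci95[2],
      tau2 = pooled$tau2,
      egger_intercept = if (is.null(egger)) NA_real_ else egger$intercept,
      egger_p = if (is.null(egger)) NA_real_ else egger$p)
  }
  per <- do.call(rbind, per)
  errs <- per$pooled_log_or - log(config$or_true)
  structure(list(per_rep = per,
                 mean_or = mean(per$pooled_or),
                 bias_log_or = mean(errs),
                 rmse_log_or = sqrt(mean(errs^2)),
                 coverage = mean(per$covered),
                 mean_tau2 = mean(per$tau2),
                 mean_egger_intercept = mean(per$egger_intercept, na.rm = TRUE),
                 mean_egger_p = mean(per$egger_p, na.rm = TRUE),
                 n_reps = n_reps, config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery over %d replicates (k = %d, true OR = %.3g, tau2 = %.3g)\n",
              x$n_reps, x$config$k_studies, x$config$or_true, x$config$tau2))
  cat(sprintf("  mean pooled OR %.4f | bias(logOR) %+.4f | RMSE %.4f\n",
              x$mean_or, x$bias_log_or, x$rmse_log_or))
  cat(sprintf("  95%% CI coverage %.3f | mean tau2 %.4f | mean Egger p %.3f\n",
              x$coverage, x$mean_tau2, x$mean_egger_p))
  invisible(x)
}
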