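# Orchestration of the full pooled analysis: per-model pooling with
# heterogeneity verdicts, subgroup analyses, cumulative and leave-one-out
# meta-analysis, bias diagnostics, and tabular report emission.

subgroup_labels <- function(estimates, axis, size_threshold = 500) {
  lab <- switch(axis,
                ethnicity = as.character(estimates$ethnicity),
                study_size = ifelse(is.na(estimates$size), NA,
                                    ifelse(estimates$size >= size_threshold,
                                           "large", "small")),
                intervention = as.character(estimates$intervention),
                ace_inhibitor = as.character(estimates$ace_inhibitor_stratum),
                stop("unknown subgroup axis: ", axis, call. = FALSE))
  lab[is.na(lab)] <- "unknown"
  lab
}

#' Subgroup meta-analysis along one stratification axis
#'
#' Runs [pool_random_dl()] independently within each level of the axis.
#' Every study lands in exactly one subgroup (missing axis values go to
#' `"unknown"`), so subgroup study counts always sum to the overall k.
#'
#' @inheritParams pool_fixed
#' @param axis One of `"ethnicity"`, `"study_size"`, `"intervention"`,
#'   `"ace_inhibitor"`.
#' @param size_threshold Total N at or above which a study is "large"
#'   (`study_size` axis only).
#' @return A named list of `"pooled_result"` objects, one per subgroup,
#'   with class `"subgroup_results"`.
#' @export
subgroup_analysis <- function(estimates, axis, size_threshold = 500) {
  check_estimates(estimates, min_k = 1, caller = "subgroup_analysis")
  lab <- subgroup_labels(estimates, axis, size_threshold)
  out <- lapply(split(seq_len(nrow(estimates)), lab), function(idx)
    pool_random_dl(estimates[idx, , drop = FALSE]))
  structure(out, class = c("subgroup_results", "list"), axis = axis)
}

#' Cumulative meta-analysis by publication year
#'
#' Orders studies chronologically and re-pools (random effects) at the end
#' of each publication year — each "information step" adds all studies of
#' that year at once. The final step reproduces the overall pooled result.
#'
#' @inheritParams pool_fixed
#' @return A data frame of class `"cumulative_meta"` with one row per
#'   distinct year: `year`, `k_so_far`, `pooled_or`, `ci_low`, `ci_high`,
#'   `p_z`, `tau2`. The full `"pooled_result"` objects are in
#'   `attr(, "pooled")`; estimates with a missing year are listed in
#'   `attr(, "excluded")`.
#' @export
cumulative_meta <- function(estimates) {
  check_estimates(estimates, min_k = 1, caller = "cumulative_meta")
  if (!"year" %in% names(estimates))
    stop("cumulative_meta needs a 'year' column", call. = FALSE)
  missing_year <- is.na(estimates$year)
  excluded <- if (any(missing_year))
    data.frame(study_id = study_ids_of(estimates)[missing_year],
               reason = "missing_year") else NULL
  est <- estimates[!missing_year, , drop = FALSE]
  if (nrow(est) == 0) stop("no estimates with a publication year", call. = FALSE)
  years <- sort(unique(est$year))
  pooled <- lapply(years, function(yr)
    pool_random_dl(est[est$year <= yr, , drop = FALSE]))
  out <- data.frame(year = years,
                    k_so_far = vapply(pooled, function(p) p$k, numeric(1)),
                    pooled_or = vapply(pooled, function(p) p$pooled_or, numeric(1)),
                    ci_low = vapply(pooled, function(p) p$ci95[1], numeric(1)),
                    ci_high = vapply(pooled, function(p) p$ci95[2], numeric(1)),
                    p_z = vapply(pooled, function(p) p$p_z, numeric(1)),
                    tau2 = vapply(pooled, function(p) p$tau2, numeric(1)))
  class(out) <- c("cumulative_meta", "data.frame")
  attr(out, "pooled") <- pooled
  attr(out, "excluded") <- excluded
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools (random effects) k times, omitting each study in turn, to show
#' whether any single study drives the pooled estimate.
#'
#' @inheritParams pool_fixed
#' @return A data frame of class `"leave_one_out"` with one row per omitted
#'   study: `omitted_study_id`, `k`, `pooled_or`, `ci_low`, `ci_high`,
#'   `p_z`, `tau2`. Full `"pooled_result"` objects in `attr(, "pooled")`.
#' @export
leave_one_out <- function(estimates) {
  check_estimates(estimates, min_k = 2, caller = "leave_one_out")
  ids <- study_ids_of(estimates)
  pooled <- lapply(seq_len(nrow(estimates)), function(i)
    pool_random_dl(estimates[-i, , drop = FALSE]))
  out <- data.frame(omitted_study_id = ids,
                    k = vapply(pooled, function(p) p$k, numeric(1)),
                    pooled_or = vapply(pooled, function(p) p$pooled_or, numeric(1)),
                    ci_low = vapply(pooled, function(p) p$ci95[1], numeric(1)),
                    ci_high = vapply(pooled, function(p) p$ci95[2], numeric(1)),
                    p_z = vapply(pooled, function(p) p$p_z, numeric(1)),
                    tau2 = vapply(pooled, function(p) p$tau2, numeric(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("leave_one_out", "data.frame")
  attr(out, "pooled") <- pooled
  out
}

#' Run the full pooled analysis on a validated cohort
#'
#' For each intervention stratum present and each of the five genetic
#' models: random-effects pooled result with heterogeneity verdict and the
#' configured subgroup analyses. The allele-model estimates of each stratum
#' additionally get funnel coordinates, Egger and Begg tests (where k
#' allows), a cumulative meta-analysis by year, and a leave-one-out
#' sensitivity analysis. Strata or subgroups with no eligible studies are
#' omitted with a diagnostic.
#'
#' @param records A `study_records` data frame (run
#'   [apply_inclusion_filters()] first if filtering is wanted).
#' @param config A [meta_config()].
#' @return A nested list of class `"meta_report"`; see [write_report()] for
#'   serialization.
#' @export
run_full_analysis <- function(records, config = meta_config()) {
  stopifnot(inherits(config, "meta_config"))
  if (nrow(records) == 0) stop("no records to analyze", call. = FALSE)
  strata <- intersect(INTERVENTIONS, unique(records$intervention))
  diagnostics <- character(0)
  result_strata <- list()
  for (iv in strata) {
    recs <- records[records$intervention == iv, , drop = FALSE]
    models <- list()
    for (m in GENETIC_MODELS) {
      est <- estimate_effects(recs, m, continuity = config$continuity)
      if (nrow(est) == 0) {
        diagnostics <- c(diagnostics,
                         sprintf("stratum '%s', model '%s': no eligible studies",
                                 iv, m))
        next
      }
      pooled <- pool_random_dl(est)
      subgroups <- lapply(config$subgroup_axes, function(ax)
        subgroup_analysis(est, ax, config$size_threshold))
      names(subgroups) <- config$subgroup_axes
      entry <- list(estimates = est, pooled = pooled,
                    heterogeneity = classify_heterogeneity(pooled, config$het_p),
                    subgroups = subgroups)
      if (m == "allele") {
        entry$funnel <- funnel_data(est)
        entry$egger <- tryCatch(egger_test(est), error = function(e) NULL)
        entry$begg <- tryCatch(begg_test(est), error = function(e) NULL)
        entry$cumulative <- tryCatch(cumulative_meta(est),
                                     error = function(e) NULL)
        entry$leave_one_out <- tryCatch(leave_one_out(est),
                                        error = function(e) NULL)
      }
      models[[m]] <- entry
    }
    result_strata[[iv]] <- models
  }
  structure(list(summary = summarize_cohort(records),
                 strata = result_strata,
                 config = config,
                 diagnostics = diagnostics),
            class = "meta_report")
}

pooled_row <- function(p) {
  data.frame(k = p$k,
             or_ci_p = format_or_ci(p$pooled_or, p$ci95, p$p_z),
             het_p_i2 = sprintf("%s; %.0f%%", format_p(p$p_q), p$i2),
             or = p$pooled_or, ci_low = p$ci95[1], ci_high = p$ci95[2],
             p_z = p$p_z, p_q = p$p_q, i2 = p$i2, tau2 = p$tau2,
             stringsAsFactors = FALSE)
}

#' Tabulate a stratum of a meta-report
#'
#' Flattens one intervention stratum into the layout of a published
#' association table: one row per genetic model and (sub)group with
#' `"OR (95% CI); P(Z)"` and `"P(Q); I2"` columns.
#'
#' @param report A `"meta_report"` from [run_full_analysis()].
#' @param stratum `"stent"` or `"balloon"` (must be present in the report).
#' @return A data frame.
#' @export
tabulate_stratum <- function(report, stratum) {
  stopifnot(inherits(report, "meta_report"))
  models <- report$strata[[stratum]]
  if (is.null(models)) stop("no stratum '", stratum, "' in report", call. = FALSE)
  rows <- list()
  for (m in names(models)) {
    e <- models[[m]]
    rows[[length(rows) + 1]] <-
      cbind(data.frame(model = m, group = "overall", stringsAsFactors = FALSE),
            pooled_row(e$pooled))
    for (ax in names(e$subgroups)) {
      sg <- e$subgroups[[ax]]
      for (g in names(sg))
        rows[[length(rows) + 1]] <-
          cbind(data.frame(model = m, group = paste0(ax, ":", g),
                           stringsAsFactors = FALSE),
                pooled_row(sg[[g]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

forest_data <- function(estimates, pooled) {
  data.frame(study_id = study_ids_of(estimates),
             or = exp(estimates$log_or),
             ci_low = exp(estimates$log_or - Z95 * estimates$se),
             ci_high = exp(estimates$log_or + Z95 * estimates$se),
             weight_pct = 100 * pooled$weights[study_ids_of(estimates)],
             stringsAsFactors = FALSE)
}

report_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "pooled_result"))
      return(x[c("model", "method", "k", "pooled_or", "ci95", "p_z",
                 "q", "p_q", "i2", "tau2")])
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  slim <- list(summary = unclass(report$summary),
               strata = lapply(report$strata, function(models)
                 lapply(models, function(e)
                   list(pooled = strip(e$pooled),
                        heterogeneity = unclass(e$heterogeneity),
                        subgroups = lapply(e$subgroups, strip),
                        egger_p = if (!is.null(e$egger)) e$egger$p,
                        begg_p = if (!is.null(e$begg)) e$begg$p))),
               diagnostics = report$diagnostics)
  jsonlite::toJSON(slim, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                   null = "null")
}

#' Write a meta-report to disk
#'
#' Emits `report.json` plus TSVs: one association table per intervention
#' stratum (`table_<stratum>.tsv`), and per stratum the allele-model
#' `funnel_<stratum>.tsv`, `cumulative_<stratum>.tsv`, `loo_<stratum>.tsv`
#' and `forest_<stratum>.tsv` (per-study OR, CI and percent weight — the
#' forest-plot data). Output is deterministic: identical report objects
#' produce byte-identical files.
#'
#' @param report A `"meta_report"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "meta_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  for (iv in names(report$strata)) {
    tsv(tabulate_stratum(report, iv), paste0("table_", iv, ".tsv"))
    al <- report$strata[[iv]][["allele"]]
    if (is.null(al)) next
    tsv(al$funnel, paste0("funnel_", iv, ".tsv"))
    if (!is.null(al$cumulative))
      tsv(as.data.frame(al$cumulative), paste0("cumulative_", iv, ".tsv"))
    if (!is.null(al$leave_one_out))
      tsv(as.data.frame(al$leave_one_out), paste0("loo_", iv, ".tsv"))
    tsv(forest_data(al$estimates, al$pooled), paste0("forest_", iv, ".tsv"))
  }
  invisible(dir)
}

#' @export
print.meta_report <- function(x, ...) {
  cat("Pooled genetic-association analysis\n")
  print(x$summary)
  for (iv in names(x$strata)) {
    cat("\n==", iv, "==\n")
    for (m in names(x$strata[[iv]])) {
      p <- x$strata[[iv]][[m]]$pooled
      cat(sprintf("  %-12s k=%2d  %s   [P(Q) %s; I2 %.0f%%]\n", m, p$k,
                  format_or_ci(p$pooled_or, p$ci95, p$p_z),
                  format_p(p$p_q), p$i2))
    }
  }
  if (length(x$diagnostics))
    cat("\ndiagnostics:\n ", paste(x$diagnostics, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
print.subgroup_results <- function(x, ...) {
  cat("subgroup analysis by", attr(x, "axis"), "\n")
  for (g in names(x)) {
    p <- x[[g]]
    cat(sprintf("  %-10s k=%2d  %s\n", g, p$k,
                format_or_ci(p$pooled_or, p$ci95, p$p_z)))
  }
  invisible(x)
}
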