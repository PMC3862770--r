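# Study-table ingestion, validation, inclusion filtering and cohort summary.
#
# The expected CSV schema carries one row per study dataset:
#   study_id, year, ethnicity {Asian, Caucasian, Other}, intervention
#   {stent, balloon}, followup_months, restenosis_definition,
#   n_case_II, n_case_ID, n_case_DD, n_ctrl_II, n_ctrl_ID, n_ctrl_DD,
#   a_case_I, a_case_D, a_ctrl_I, a_ctrl_D, cases_total, controls_total,
#   mean_age, pct_male, quality {High, Median, Poor}, ace_inhibitor_stratum
#   {treated, untreated, unstratified}
# Genotype counts refer to the II / ID / DD classes of a biallelic
# insertion-deletion (or SNP) locus; allele-only studies report I/D allele
# counts instead. Missing values are empty cells or "NA"; counts are never
# silently coerced to zero.

MANDATORY_COLS <- c("study_id", "year", "ethnicity", "intervention")
GENO_CASE <- c("n_case_II", "n_case_ID", "n_case_DD")
GENO_CTRL <- c("n_ctrl_II", "n_ctrl_ID", "n_ctrl_DD")
ALLELE_COLS <- c("a_case_I", "a_case_D", "a_ctrl_I", "a_ctrl_D")
COUNT_COLS <- c(GENO_CASE, GENO_CTRL, ALLELE_COLS, "cases_total", "controls_total")
OPTIONAL_COLS <- c("followup_months", "restenosis_definition", COUNT_COLS,
                   "mean_age", "pct_male", "quality", "ace_inhibitor_stratum")
ETHNICITIES <- c("Asian", "Caucasian", "Other")
INTERVENTIONS <- c("stent", "balloon")
QUALITIES <- c("High", "Median", "Poor")
ACE_STRATA <- c("treated", "untreated", "unstratified")

row_problems <- function(r) {
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)
  if (is.na(r$study_id) || !nzchar(r$study_id)) add("missing study_id")
  if (is.na(r$year)) add("missing year")
  if (!is.na(r$ethnicity) && !r$ethnicity %in% ETHNICITIES)
    add(paste0("ethnicity '", r$ethnicity, "' not one of ",
               paste(ETHNICITIES, collapse = "/")))
  if (is.na(r$intervention) || !r$intervention %in% INTERVENTIONS)
    add(paste0("intervention '", r$intervention, "' not one of ",
               paste(INTERVENTIONS, collapse = "/")))
  if (!is.na(r$quality) && !r$quality %in% QUALITIES)
    add(paste0("quality '", r$quality, "' not one of ",
               paste(QUALITIES, collapse = "/")))
  if (!is.na(r$ace_inhibitor_stratum) && !r$ace_inhibitor_stratum %in% ACE_STRATA)
    add("invalid ace_inhibitor_stratum")
  for (col in COUNT_COLS) {
    v <- r[[col]]
    if (!is.na(v) && !is_count(v)) add(paste0(col, " = ", v, " is not a non-negative integer"))
  }
  if (!is.na(r$followup_months) && r$followup_months <= 0)
    add("followup_months must be positive")
  if (!is.na(r$pct_male) && (r$pct_male < 0 || r$pct_male > 100))
    add("pct_male outside [0, 100]")
  # each arm: genotype counts all present or all absent
  for (arm in list(case = GENO_CASE, ctrl = GENO_CTRL)) {
    pres <- !vapply(arm, function(cl) is.na(r[[cl]]), logical(1))
    if (any(pres) && !all(pres))
      add(paste0("partial genotype counts in ", paste(arm[!pres], collapse = ",")))
  }
  # allele counts come in case and control pairs
  for (pair in list(c("a_case_I", "a_case_D"), c("a_ctrl_I", "a_ctrl_D"))) {
    pres <- !vapply(pair, function(cl) is.na(r[[cl]]), logical(1))
    if (any(pres) && !all(pres))
      add(paste0("partial allele counts in ", paste(pair[!pres], collapse = ",")))
  }
  if (!length(probs)) {
    # cross-field consistency, only checked on otherwise-typed rows
    chk_arm <- function(geno, aI, aD, tot, arm) {
      g <- unlist(r[geno])
      if (!anyNA(g)) {
        if (!is.na(r[[aI]]) && r[[aI]] != 2 * g[1] + g[2])
          add(paste0(arm, " I allele count disagrees with genotypes (expect ",
                     2 * g[1] + g[2], ")"))
        if (!is.na(r[[aD]]) && r[[aD]] != 2 * g[3] + g[2])
          add(paste0(arm, " D allele count disagrees with genotypes (expect ",
                     2 * g[3] + g[2], ")"))
        if (!is.na(r[[tot]]) && r[[tot]] != sum(g))
          add(paste0(arm, " total disagrees with genotype sum ", sum(g)))
      }
    }
    chk_arm(GENO_CASE, "a_case_I", "a_case_D", "cases_total", "case")
    chk_arm(GENO_CTRL, "a_ctrl_I", "a_ctrl_D", "controls_total", "control")
  }
  probs
}

#' Load a study-characteristics table
#'
#' Reads a CSV of per-study metadata and genotype (or allele) counts,
#' validates every row against the documented schema, and returns a
#' `study_records` data frame. Rows failing validation are either reported
#' as an error (`strict = TRUE`, default) or dropped with row-level
#' diagnostics attached as `attr(, "rejected")`.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#'   Missing values are empty cells or `"NA"`.
#' @param strict If `TRUE`, any invalid row aborts with a message naming the
#'   row and problem; if `FALSE`, invalid rows are dropped and reported.
#' @return A data frame of class `c("study_records", "data.frame")` with one
#'   row per dataset. `cases_total`/`controls_total` are filled in from
#'   genotype or allele sums where absent. Control-arm HWE columns
#'   (`hwe_p`, `hwe_violation`) are added via [add_hwe_flags()].
#' @seealso [apply_inclusion_filters()], [summarize_cohort()], [write_studies()]
#' @examples
#' path <- system.file("extdata", "ptca_restenosis_studies.csv",
#'                     package = "genassocmeta")
#' studies <- load_studies(path)
#' nrow(studies)
#' @export
load_studies <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("studies file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols))
    stop("studies file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in OPTIONAL_COLS) if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  df$study_id <- as.character(df$study_id)
  for (col in c("year", COUNT_COLS)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in c("followup_months", "mean_age", "pct_male"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (nrow(df) == 0) return(as_study_records(df))

  probs <- lapply(seq_len(nrow(df)), function(i) row_problems(df[i, , drop = FALSE]))
  bad <- lengths(probs) > 0
  if (any(bad)) {
    msgs <- vapply(which(bad), function(i)
      paste0("row ", i, " (", df$study_id[i], "): ",
             paste(probs[[i]], collapse = "; ")), character(1))
    if (strict)
      stop("invalid study rows:\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
    rejected <- data.frame(row = which(bad), study_id = df$study_id[bad],
                           reason = vapply(probs[bad], paste, character(1),
                                           collapse = "; "))
    df <- df[!bad, , drop = FALSE]
    out <- as_study_records(df)
    attr(out, "rejected") <- rejected
    return(out)
  }
  as_study_records(df)
}

as_study_records <- function(df) {
  rownames(df) <- NULL
  # fill arm totals from whichever counts are available
  gsum <- function(cols) {
    if (!nrow(df)) return(numeric(0))
    rowSums(df[, cols, drop = FALSE])
  }
  case_geno <- gsum(GENO_CASE); ctrl_geno <- gsum(GENO_CTRL)
  case_all <- (df$a_case_I + df$a_case_D) / 2
  ctrl_all <- (df$a_ctrl_I + df$a_ctrl_D) / 2
  df$cases_total <- ifelse(!is.na(df$cases_total), df$cases_total,
                           ifelse(!is.na(case_geno), case_geno, case_all))
  df$controls_total <- ifelse(!is.na(df$controls_total), df$controls_total,
                              ifelse(!is.na(ctrl_geno), ctrl_geno, ctrl_all))
  df$has_genotypes <- !is.na(case_geno) & !is.na(ctrl_geno)
  df$has_alleles <- !is.na(df$a_case_I) & !is.na(df$a_ctrl_I)
  class(df) <- c("study_records", "data.frame")
  add_hwe_flags(df)
}

#' Write a study-characteristics table
#'
#' Inverse of [load_studies()]: writes the schema columns as CSV so that a
#' load/write/load round trip is the identity on all fields.
#'
#' @param records A `study_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(records, path) {
  cols <- c(MANDATORY_COLS, OPTIONAL_COLS)
  keep <- c(cols, setdiff(names(records),
                          c(cols, "has_genotypes", "has_alleles",
                            "hwe_p", "hwe_chi2", "hwe_violation")))
  utils::write.csv(as.data.frame(records)[, intersect(keep, names(records)),
                                          drop = FALSE],
                   path, row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Test genotype counts for Hardy-Weinberg equilibrium
#'
#' Pearson chi-square goodness-of-fit of observed II/ID/DD genotype counts
#' against the proportions \eqn{(1-p)^2, 2p(1-p), p^2} expected at the
#' estimated D-allele frequency \eqn{p = (2\,DD + ID) / 2N}, on 1 degree of
#' freedom (one allele frequency estimated from three classes).
#'
#' @param n_II,n_ID,n_DD Non-negative integer genotype counts.
#' @return An object of class `"hwe_result"`: a list with `chi2`, `df`,
#'   `p_value`, and `allele_freq_D`.
#' @examples
#' hwe_test(30, 40, 30)   # chi2 = 4, p ~ 0.0455
#' @export
hwe_test <- function(n_II, n_ID, n_DD) {
  counts <- c(n_II, n_ID, n_DD)
  if (length(counts) != 3 || anyNA(counts) || !all(is_count(counts)))
    stop("hwe_test needs three non-negative integer genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("hwe_test: total genotype count is zero", call. = FALSE)
  p <- (2 * n_DD + n_ID) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  # monomorphic sample: observed == expected exactly, no departure testable
  if (p == 0 || p == 1) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 allele_freq_D = p),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (df = %d), p = %s, D freq = %.3f\n",
              x$chi2, x$df, format_p(x$p_value), x$allele_freq_D))
  invisible(x)
}

#' Flag control-arm departures from Hardy-Weinberg equilibrium
#'
#' Adds `hwe_chi2`, `hwe_p` and `hwe_violation` columns computed from the
#' control genotype counts (NA where controls have no genotype counts).
#' A deviation flags the record; it does not exclude it unless
#' `exclude_hwe_violations` is enabled in the configuration passed to
#' [apply_inclusion_filters()].
#'
#' @param records A `study_records` data frame.
#' @param alpha Flagging level, default 0.05.
#' @return `records` with the three columns added/refreshed.
#' @export
add_hwe_flags <- function(records, alpha = 0.05) {
  n <- nrow(records)
  chi2 <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- unlist(records[i, GENO_CTRL])
    if (!anyNA(g) && sum(g) > 0) {
      h <- hwe_test(g[1], g[2], g[3])
      chi2[i] <- h$chi2; p[i] <- h$p_value
    }
  }
  records$hwe_chi2 <- chi2
  records$hwe_p <- p
  records$hwe_violation <- !is.na(p) & p < alpha
  records
}

#' Apply the cohort inclusion filters
#'
#' Drops records whose recorded angiographic follow-up falls outside the
#' window (restenosis is time-related, so only a bounded follow-up window is
#' comparable across studies), records carrying neither genotype nor allele
#' counts, and — optionally — records whose controls violate HWE.
#' Records with a missing follow-up are retained: the filter applies only
#' where the field is present.
#'
#' @param records A `study_records` data frame.
#' @param config A [meta_config()]; its `followup_window`, `hwe_alpha` and
#'   `exclude_hwe_violations` fields drive the filtering.
#' @return A list with elements `kept` (a `study_records` data frame) and
#'   `dropped` (a data frame with `study_id` and `reason`, one of
#'   `"followup_window"`, `"no_counts"`, `"hwe_violation"`).
#' @examples
#' path <- system.file("extdata", "ptca_restenosis_studies.csv",
#'                     package = "genassocmeta")
#' f <- apply_inclusion_filters(load_studies(path))
#' f$dropped   # the 5.2-year follow-up cohort falls outside 3-12 months
#' @export
apply_inclusion_filters <- function(records, config = meta_config()) {
  stopifnot(inherits(config, "meta_config"))
  win <- config$followup_window
  records <- add_hwe_flags(records, config$hwe_alpha)
  reason <- rep(NA_character_, nrow(records))
  out_of_window <- !is.na(records$followup_months) &
    (records$followup_months < win[1] | records$followup_months > win[2])
  reason[out_of_window] <- "followup_window"
  no_counts <- !records$has_genotypes & !records$has_alleles
  reason[is.na(reason) & no_counts] <- "no_counts"
  if (config$exclude_hwe_violations)
    reason[is.na(reason) & records$hwe_violation] <- "hwe_violation"
  drop <- !is.na(reason)
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       dropped = data.frame(study_id = records$study_id[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE))
}

#' Summarize a study cohort
#'
#' Totals and tallies in the shape of a study-characteristics table footer:
#' dataset and distinct-study counts, case/control/patient totals overall
#' and per intervention stratum, and the quality-label tally.
#'
#' @param records A `study_records` data frame (possibly empty).
#' @return An object of class `"cohort_summary"`.
#' @examples
#' path <- system.file("extdata", "ptca_restenosis_studies.csv",
#'                     package = "genassocmeta")
#' summarize_cohort(load_studies(path))
#' @export
summarize_cohort <- function(records) {
  cases <- records$cases_total
  ctrls <- records$controls_total
  by_iv <- lapply(INTERVENTIONS, function(iv) {
    sel <- !is.na(records$intervention) & records$intervention == iv
    c(cases = sum(cases[sel], na.rm = TRUE),
      controls = sum(ctrls[sel], na.rm = TRUE))
  })
  names(by_iv) <- INTERVENTIONS
  qual <- table(factor(records$quality, levels = QUALITIES))
  structure(list(n_studies = length(unique(records$study_id)),
                 n_datasets = nrow(records),
                 total_cases = sum(cases, na.rm = TRUE),
                 total_controls = sum(ctrls, na.rm = TRUE),
                 total_patients = sum(cases, na.rm = TRUE) + sum(ctrls, na.rm = TRUE),
                 counts_by_quality = stats::setNames(as.integer(qual), names(qual)),
                 counts_by_intervention = by_iv),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d datasets from %d studies: %d cases / %d controls (%d patients)\n",
              x$n_datasets, x$n_studies, x$total_cases, x$total_controls,
              x$total_patients))
  for (iv in names(x$counts_by_intervention)) {
    v <- x$counts_by_intervention[[iv]]
    cat(sprintf("  %-8s %6d cases / %6d controls\n", iv, v["cases"], v["controls"]))
  }
  q <- x$counts_by_quality
  cat("  quality:", paste(sprintf("%s=%d", names(q), q), collapse = ", "), "\n")
  invisible(x)
}
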