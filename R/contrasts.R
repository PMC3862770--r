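# Five genetic-model contrasts for a biallelic I/D locus.
#
# Exposure is always the D-associated category:
#   allele:       D allele vs I allele (2 alleles per person)
#   dominant:     DD + ID  vs II
#   recessive:    DD       vs ID + II
#   heterozygous: ID       vs II   (DD class discarded)
#   homozygous:   DD       vs II   (ID class discarded)

GENETIC_MODELS <- c("allele", "dominant", "recessive", "heterozygous", "homozygous")

#' The five genetic model names
#'
#' @return Character vector: allele, dominant, recessive, heterozygous,
#'   homozygous.
#' @export
genetic_models <- function() GENETIC_MODELS

model_cells <- function(II, ID, DD, model) {
  switch(model,
         allele       = c(exposed = 2 * DD + ID, unexposed = 2 * II + ID),
         dominant     = c(exposed = DD + ID, unexposed = II),
         recessive    = c(exposed = DD, unexposed = ID + II),
         heterozygous = c(exposed = ID, unexposed = II),
         homozygous   = c(exposed = DD, unexposed = II),
         stop("unknown genetic model: ", model, call. = FALSE))
}

#' Build the 2x2 contingency table for one study under a genetic model
#'
#' Cell layout follows the conventional exposure-by-outcome table:
#' `a` = exposed cases, `b` = unexposed cases, `c` = exposed controls,
#' `d` = unexposed controls. Allele-only studies (no genotype breakdown)
#' are eligible for the allele contrast only.
#'
#' @param record One row of a `study_records` data frame (or a list with the
#'   same fields).
#' @param model One of [genetic_models()].
#' @return A list of class `"contrast_table"` with fields `study_id`,
#'   `model`, `a`, `b`, `c`, `d`, `corrected` (FALSE until
#'   [continuity_correct()] acts).
#' @examples
#' rec <- list(study_id = "s1", n_case_II = 10, n_case_ID = 20, n_case_DD = 10,
#'             n_ctrl_II = 30, n_ctrl_ID = 20, n_ctrl_DD = 10)
#' build_contrast(rec, "dominant")
#' @export
build_contrast <- function(record, model = genetic_models()) {
  model <- match.arg(model)
  record <- as.list(record)
  geno <- unlist(record[c(GENO_CASE, GENO_CTRL)])
  has_geno <- length(geno) == 6 && !anyNA(geno)
  if (has_geno) {
    cs <- model_cells(record$n_case_II, record$n_case_ID, record$n_case_DD, model)
    ct <- model_cells(record$n_ctrl_II, record$n_ctrl_ID, record$n_ctrl_DD, model)
    cells <- c(a = unname(cs["exposed"]), b = unname(cs["unexposed"]),
               c = unname(ct["exposed"]), d = unname(ct["unexposed"]))
  } else if (model == "allele" &&
             !anyNA(unlist(record[ALLELE_COLS]))) {
    cells <- c(a = record$a_case_D, b = record$a_case_I,
               c = record$a_ctrl_D, d = record$a_ctrl_I)
  } else {
    stop("study '", record$study_id, "' lacks genotype counts and is only ",
         "eligible for the allele contrast", call. = FALSE)
  }
  structure(c(list(study_id = record$study_id %||% NA_character_,
                   model = model),
              as.list(cells), list(corrected = FALSE)),
            class = "contrast_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Continuity-correct a 2x2 table with zero cells
#'
#' If any of the four cells is zero, the constant (default 0.5,
#' Haldane-Anscombe) is added to all four cells of this table; tables with
#' no zero cell are returned unchanged. A table whose four cells are all
#' zero carries no information and raises a `noninformative_study` error so
#' that callers exclude it with a diagnostic.
#'
#' @param table A `"contrast_table"`.
#' @param constant Positive correction constant.
#' @return The (possibly corrected) `"contrast_table"`, with `corrected`
#'   set accordingly.
#' @export
continuity_correct <- function(table, constant = 0.5) {
  stopifnot(inherits(table, "contrast_table"), constant > 0)
  cells <- c(table$a, table$b, table$c, table$d)
  if (all(cells == 0)) {
    cond <- structure(class = c("noninformative_study", "error", "condition"),
                      list(message = paste0("study '", table$study_id,
                                            "' has an all-zero ", table$model,
                                            " table and is non-informative"),
                           call = NULL))
    stop(cond)
  }
  if (any(cells == 0)) {
    table$a <- table$a + constant; table$b <- table$b + constant
    table$c <- table$c + constant; table$d <- table$d + constant
    table$corrected <- TRUE
  }
  table
}

#' Per-study log odds ratio with Woolf variance
#'
#' \eqn{\log OR = \log(ad/bc)} with standard error
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}. All four cells must be positive:
#' run [continuity_correct()] first.
#'
#' @param table A `"contrast_table"` with positive cells.
#' @return A list of class `"effect_estimate"`: `study_id`, `model`,
#'   `log_or`, `se`.
#' @examples
#' t <- structure(list(study_id = "s", model = "allele", a = 20, b = 10,
#'                     c = 10, d = 20, corrected = FALSE),
#'                class = "contrast_table")
#' estimate_effect(t)   # OR = 4
#' @export
estimate_effect <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells <= 0))
    stop("estimate_effect: zero cell in table for study '", table$study_id,
         "'; apply continuity_correct() first", call. = FALSE)
  structure(list(study_id = table$study_id, model = table$model,
                 log_or = log(table$a * table$d / (table$b * table$c)),
                 se = sqrt(sum(1 / cells))),
            class = "effect_estimate")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("%s contrast for '%s'%s\n", x$model, x$study_id,
              if (x$corrected) " (continuity-corrected)" else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"), c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Per-study effect estimates for a whole cohort
#'
#' Applies [build_contrast()], [continuity_correct()] and
#' [estimate_effect()] across all eligible records, carrying along the
#' study-level covariates used by subgroup analysis and meta-regression.
#' Ineligible records (genotype-based model requested of an allele-only
#' study) and non-informative tables are skipped with a diagnostic.
#'
#' @param records A `study_records` data frame.
#' @param model One of [genetic_models()].
#' @param continuity Continuity-correction constant.
#' @return A data frame of class `c("effect_estimates", "data.frame")` with
#'   columns `study_id`, `model`, `log_or`, `se`, `corrected`, `year`,
#'   `ethnicity`, `intervention`, `size` (total N), `followup_months`,
#'   `mean_age`, `pct_male`, `ace_inhibitor_stratum`. Skipped records are
#'   listed in `attr(, "skipped")`.
#' @export
estimate_effects <- function(records, model = genetic_models(), continuity = 0.5) {
  model <- match.arg(model)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, , drop = FALSE])
    est <- tryCatch({
      tab <- continuity_correct(build_contrast(rec, model), continuity)
      c(estimate_effect(tab)[c("study_id", "model", "log_or", "se")],
        corrected = tab$corrected)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(study_id = rec$study_id,
                   reason = if (inherits(est, "noninformative_study"))
                     "non_informative" else "ineligible",
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      study_id = est$study_id, model = est$model, log_or = est$log_or,
      se = est$se, corrected = est$corrected,
      year = rec$year %||% NA, ethnicity = rec$ethnicity %||% NA,
      intervention = rec$intervention %||% NA,
      size = (rec$cases_total %||% NA) + (rec$controls_total %||% NA),
      followup_months = rec$followup_months %||% NA,
      mean_age = rec$mean_age %||% NA, pct_male = rec$pct_male %||% NA,
      ace_inhibitor_stratum = rec$ace_inhibitor_stratum %||% NA,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(0), model = character(0),
               log_or = numeric(0), se = numeric(0), corrected = logical(0))
  rownames(out) <- NULL
  class(out) <- c("effect_estimates", "data.frame")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}
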