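#' Analysis configuration
#'
#' Collects the tunable thresholds of the pipeline in one object. All
#' arguments have the defaults used throughout the package; any subset can
#' be overridden, including from a YAML or JSON file via [read_config()].
#'
#' @param followup_window Numeric length-2, the admissible angiographic
#'   follow-up interval in months. Records with a recorded follow-up outside
#'   this window are excluded by [apply_inclusion_filters()]. Durations
#'   reported in years must be converted to months (multiply by 12) before
#'   they enter a study table.
#' @param continuity Continuity-correction constant added to all four cells
#'   of a 2x2 table containing a zero cell (Haldane-Anscombe).
#' @param size_threshold Total sample size (cases + controls) at or above
#'   which a study is classed "large" in the study-size subgroup axis.
#' @param hwe_alpha Significance level for flagging departure from
#'   Hardy-Weinberg equilibrium in controls.
#' @param exclude_hwe_violations If `TRUE`, records whose controls violate
#'   HWE at `hwe_alpha` are excluded by [apply_inclusion_filters()]; by
#'   default they are only flagged.
#' @param het_p Significance threshold for the heterogeneity Q test.
#' @param subgroup_axes Character vector of subgroup axes computed by
#'   [run_full_analysis()]. Any of `"ethnicity"`, `"study_size"`,
#'   `"intervention"`, `"ace_inhibitor"`.
#' @return A list of class `"meta_config"`.
#' @examples
#' cfg <- meta_config(size_threshold = 300)
#' cfg$size_threshold
#' @export
meta_config <- function(followup_window = c(3, 12),
                        continuity = 0.5,
                        size_threshold = 500,
                        hwe_alpha = 0.05,
                        exclude_hwe_violations = FALSE,
                        het_p = 0.10,
                        subgroup_axes = c("ethnicity", "study_size")) {
  stopifnot(length(followup_window) == 2, followup_window[1] <= followup_window[2],
            continuity > 0, size_threshold > 0,
            hwe_alpha > 0, hwe_alpha < 1, het_p > 0, het_p < 1)
  axes <- match.arg(subgroup_axes,
                    c("ethnicity", "study_size", "intervention", "ace_inhibitor"),
                    several.ok = TRUE)
  structure(list(followup_window = as.numeric(followup_window),
                 continuity = continuity,
                 size_threshold = size_threshold,
                 hwe_alpha = hwe_alpha,
                 exclude_hwe_violations = isTRUE(exclude_hwe_violations),
                 het_p = het_p,
                 subgroup_axes = axes),
            class = "meta_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields not present in the file keep their [meta_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"meta_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(meta_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unknown config fields: ", paste(extra, collapse = ", "),
            call. = FALSE)
  do.call(meta_config, raw[intersect(names(raw), known)])
}

#' @export
print.meta_config <- function(x, ...) {
  cat("Meta-analysis configuration\n")
  cat("  follow-up window [months]:", x$followup_window[1], "-",
      x$followup_window[2], "\n")
  cat("  continuity constant:      ", x$continuity, "\n")
  cat("  large-study threshold (N):", x$size_threshold, "\n")
  cat("  HWE alpha:                ", x$hwe_alpha,
      if (x$exclude_hwe_violations) "(violations excluded)" else "(violations flagged)", "\n")
  cat("  heterogeneity P threshold:", x$het_p, "\n")
  cat("  subgroup axes:            ", paste(x$subgroup_axes, collapse = ", "), "\n")
  invisible(x)
}
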