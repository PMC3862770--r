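#' @keywords internal
"_PACKAGE"

# Normal quantile used for all 95% intervals on the log-OR scale.
Z95 <- stats::qnorm(0.975)

is_count <- function(x) {
  !is.na(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' Format a p-value the way meta-analysis tables print them
#'
#' Three significant figures, switching to `"<10^-4"` below 1e-4.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector.
#' @examples
#' format_p(c(0.006, 0.25, 3e-6))
#' @export
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "<10^-4"
    else format(signif(pi, 3), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Format an odds ratio with its confidence interval and p-value
#'
#' Produces the `"1.31 (1.08-1.58); 0.006"` layout used in published
#' association tables.
#'
#' @param or Pooled odds ratio.
#' @param ci Length-2 numeric vector, the 95% CI on the OR scale.
#' @param p Two-sided p-value for the OR.
#' @param digits Digits after the decimal point for OR and CI.
#' @return A single character string.
#' @export
format_or_ci <- function(or, ci, p, digits = 2) {
  sprintf("%.*f (%.*f-%.*f); %s", digits, or, digits, ci[1], digits, ci[2],
          format_p(p))
}

# Validate an estimates data.frame (log_or + se columns).
check_estimates <- function(estimates, min_k = 1, caller = "pooling") {
  if (!is.data.frame(estimates) || !all(c("log_or", "se") %in% names(estimates)))
    stop(caller, " expects a data.frame with columns 'log_or' and 'se'",
         call. = FALSE)
  if (nrow(estimates) < min_k)
    stop(caller, " requires at least ", min_k, " studies, got ",
         nrow(estimates), call. = FALSE)
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0))
    stop("all standard errors must be finite and positive", call. = FALSE)
  if (any(!is.finite(estimates$log_or)))
    stop("all log odds ratios must be finite", call. = FALSE)
  invisible(estimates)
}

study_ids_of <- function(estimates) {
  if ("study_id" %in% names(estimates)) as.character(estimates$study_id)
  else sprintf("study_%02d", seq_len(nrow(estimates)))
}
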