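# Within-run quality control: replicate %CV, the automatic high-CV flagging
# rule, exclusions with recomputation, and positivity calls.

#' Percent coefficient of variation of replicate values
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector of replicate FIs.
#' @return The %CV, or `NA` when fewer than two values are supplied or the
#'   mean is zero (the latter with a warning).
#' @export
percent_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) {
    warn("replicate mean is zero; %CV is undefined")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' High replicate-CV flagging rule
#'
#' A replicate group is flagged when its reported FI exceeds the FI gate
#' (default 100) *and* its %CV exceeds the role-specific limit: 15 for
#' unknowns, 20 for standards and quality controls. The FI gate saves review
#' time: only potentially positive samples warrant investigation. Both
#' comparisons are strict. Background groups are never flagged.
#'
#' @param mean_fi Replicate-group mean FI.
#' @param pct_cv Replicate-group %CV.
#' @param role Sample role (`"unknown"`, `"standard"`, `"qc_control"`,
#'   `"background"`).
#' @param fi_gate FI threshold below which no flag is raised.
#' @param limit_unknown,limit_titration %CV limits for unknowns and for
#'   standards/quality controls.
#' @return `TRUE` if the group is flagged.
#' @export
flag_high_cv <- function(mean_fi, pct_cv, role, fi_gate = 100,
                         limit_unknown = 15, limit_titration = 20) {
  if (is.na(mean_fi) || is.na(pct_cv)) return(FALSE)
  limit <- switch(role,
                  unknown = limit_unknown,
                  standard = limit_titration,
                  qc_control = limit_titration,
                  control = limit_titration,
                  return(FALSE))
  mean_fi > fi_gate && pct_cv > limit
}

#' Create an exclusion record
#'
#' Exclusions remove data from analysis without deleting it: excluded rows
#' stay in every output, marked by status columns. Scope is either a whole
#' analyte or one replicate group (sample + dilution within an analyte).
#'
#' @param scope `"analyte"` or `"replicate_group"`.
#' @param analyte Analyte name.
#' @param sample_id,description,dilution Replicate-group key (required for
#'   `scope = "replicate_group"`).
#' @param reason Free-text reason, kept for review.
#' @return An object of class `xmap_exclusion`.
#' @export
exclusion <- function(scope = c("analyte", "replicate_group"), analyte,
                      sample_id = NULL, description = NULL, dilution = NULL,
                      reason = "") {
  scope <- match.arg(scope)
  if (scope == "replicate_group" && is.null(sample_id)) {
    stop_usage("`sample_id` is required for replicate-group exclusions")
  }
  structure(list(scope = scope, analyte = analyte, sample_id = sample_id,
                 description = description, dilution = dilution,
                 reason = reason, timestamp = format(Sys.time(), tz = "UTC")),
            class = "xmap_exclusion")
}

# logical vector: which wells of `wells` does `excl` target
exclusion_matches <- function(wells, excl) {
  hit <- wells$analyte == excl$analyte
  if (excl$scope == "replicate_group") {
    hit <- hit & wells$sample_id == excl$sample_id
    if (!is.null(excl$description)) {
      hit <- hit & (is.na(wells$description) | wells$description == excl$description)
    }
    if (!is.null(excl$dilution)) hit <- hit & wells$dilution == excl$dilution
  }
  hit & !is.na(wells$analyte)
}

#' Positivity call for one measurement
#'
#' A value is called positive when it has increased at least `fold_change`
#' times over its baseline *and* exceeds the analyte-specific threshold.
#' The baseline and threshold are user-supplied per sample/analyte; the
#' fold-change magnitude is a user parameter (default 3).
#'
#' @param value Observed value (e.g. replicate-group mean FI).
#' @param baseline Baseline value for the same sample and analyte.
#' @param threshold Analyte-specific positivity threshold.
#' @param fold_change Required fold increase over baseline (>= 1).
#' @return `TRUE`, `FALSE`, or `NA` (with a warning) when baseline or
#'   threshold is missing.
#' @export
positivity_call <- function(value, baseline, threshold, fold_change = 3) {
  if (fold_change < 1) stop_domain("`fold_change` must be >= 1")
  if (is.null(baseline) || is.null(threshold) || is.na(baseline) || is.na(threshold)) {
    warn("missing baseline or threshold; positivity call is undefined")
    return(NA)
  }
  value >= fold_change * baseline && value > threshold
}
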