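# Cross-run quality control: guide sets of baseline runs define expected
# ranges (mean +/- 1, 2, 3 SD) for the four curve metrics (4pl EC50,
# 5pl EC50, AUC, HighMFI); later runs sharing the same lot scope are
# flagged when a metric falls strictly outside the +/- 3 SD band.

CROSSRUN_METRICS <- c("ec50_4pl", "ec50_5pl", "auc", "high_mfi")

lot_scope_of <- function(row) {
  list(reagent_lot = row$reagent_lot, isotype = row$isotype,
       conjugate = row$conjugate)
}

same_lot_scope <- function(a, b) {
  identical(a$reagent_lot, b$reagent_lot) && identical(a$isotype, b$isotype) &&
    identical(a$conjugate, b$conjugate)
}

#' Build a guide set from baseline runs
#'
#' Guide-set membership is explicit: the user names the baseline runs. Per
#' metric, the mean and sample (n-1) SD are computed over the member runs
#' where that metric is present; the SD is undefined (and outlier flagging
#' disabled, with a warning) when fewer than two members carry the metric.
#'
#' @param metrics Tibble of per-run metrics as returned by [run_metrics()],
#'   restricted to one analyte and titration role.
#' @param member_run_ids Run ids of the baseline runs.
#' @return An object of class `xmap_guide_set`.
#' @export
build_guide_set <- function(metrics, member_run_ids) {
  mm <- metrics[metrics$run_id %in% member_run_ids, , drop = FALSE]
  if (nrow(mm) == 0L) stop_usage("no metric rows match the requested member runs")
  if (length(unique(mm$analyte)) > 1L || length(unique(mm$titration)) > 1L) {
    stop_usage("guide-set members must share one analyte and titration")
  }
  scopes <- unique(mm[, c("reagent_lot", "isotype", "conjugate")])
  if (nrow(scopes) > 1L) {
    stop_usage("guide-set members must share one lot scope (reagent lot, isotype, conjugate)")
  }
  stats <- lapply(CROSSRUN_METRICS, function(met) {
    v <- mm[[met]]
    v <- v[is.finite(v)]
    tibble::tibble(metric = met, n = length(v),
                   mu = if (length(v) >= 1L) mean(v) else NA_real_,
                   sigma = if (length(v) >= 2L) sd(v) else NA_real_)
  })
  stats <- dplyr::bind_rows(stats)
  if (any(stats$n > 0 & stats$n < 2)) {
    warn("guide set has a single member for some metric(s); SD undefined, outlier flagging disabled for those")
  }
  structure(list(analyte = mm$analyte[1], titration = mm$titration[1],
                 lot_scope = lot_scope_of(mm[1, ]),
                 members = unique(mm$run_id), stats = stats),
            class = "xmap_guide_set")
}

#' @export
print.xmap_guide_set <- function(x, ...) {
  cat(sprintf("<xmap_guide_set> %s / %s, lot '%s', %d member run(s)\n",
              x$analyte, x$titration, x$lot_scope$reagent_lot, length(x$members)))
  print(x$stats)
  invisible(x)
}

#' Expected ranges for a guide-set metric
#'
#' @param gs An `xmap_guide_set`.
#' @param metric One of `"ec50_4pl"`, `"ec50_5pl"`, `"auc"`, `"high_mfi"`.
#' @return Tibble of nested bands `mu +/- k sigma` for k = 1, 2, 3, or
#'   `NULL` when the SD is undefined.
#' @export
expected_ranges <- function(gs, metric) {
  st <- gs$stats[gs$stats$metric == metric, , drop = FALSE]
  if (nrow(st) != 1L) stop_usage(sprintf("unknown metric '%s'", metric))
  if (!is.finite(st$sigma)) return(NULL)
  tibble::tibble(metric = metric, k = 1:3, mu = st$mu, sigma = st$sigma,
                 lower = st$mu - (1:3) * st$sigma,
                 upper = st$mu + (1:3) * st$sigma)
}

#' Flag a run's metrics against a guide set
#'
#' Each of the four metrics present on the run is flagged when it falls
#' strictly outside the maximum expected range `mu +/- 3 sigma`; a value
#' exactly on the boundary is inside. Guide-set member runs are never
#' flagged against their own set.
#'
#' @param run_row One row of a [run_metrics()] tibble.
#' @param gs The applicable `xmap_guide_set`.
#' @return Tibble of flags (possibly empty): `flag_id`, `run_id`, `metric`,
#'   `value`, `mu`, `sigma`, `kind`, `rule`, `active`, `comment`.
#' @export
flag_metrics <- function(run_row, gs) {
  empty <- tibble::tibble(flag_id = character(), run_id = character(),
                          metric = character(), value = double(),
                          mu = double(), sigma = double(), kind = character(),
                          rule = character(), active = logical(),
                          comment = character())
  if (!inherits(gs, "xmap_guide_set")) {
    warn("no applicable guide set; no cross-run flags raised")
    return(empty)
  }
  if (run_row$analyte != gs$analyte || run_row$titration != gs$titration ||
      !same_lot_scope(lot_scope_of(run_row), gs$lot_scope)) {
    warn("guide set does not apply to this run's analyte/titration/lot; no flags raised")
    return(empty)
  }
  if (run_row$run_id %in% gs$members) return(empty)
  rows <- list()
  for (met in CROSSRUN_METRICS) {
    v <- run_row[[met]]
    st <- gs$stats[gs$stats$metric == met, ]
    if (!is.finite(v) || !is.finite(st$sigma)) next
    lo <- st$mu - 3 * st$sigma
    hi <- st$mu + 3 * st$sigma
    if (v < lo || v > hi) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        flag_id = sprintf("%s/%s/%s/%s", run_row$run_id, gs$analyte, gs$titration, met),
        run_id = run_row$run_id, metric = met, value = v,
        mu = st$mu, sigma = st$sigma, kind = "guideset_outlier",
        rule = sprintf("outside %.6g +/- 3*%.6g", st$mu, st$sigma),
        active = TRUE, comment = "")
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty
}

#' Inactivate a reviewed quality-control flag
#'
#' Inactivation preserves the record: the flag row stays, with
#' `active = FALSE` and the reviewer's comment. Idempotent.
#'
#' @param flags Flag tibble (from [flag_metrics()] or accumulated).
#' @param flag_id Identifier of the flag to inactivate.
#' @param comment Reviewer comment recorded with the inactivation.
#' @return The updated flag tibble.
#' @export
inactivate_flag <- function(flags, flag_id, comment = "") {
  i <- which(flags$flag_id == flag_id)
  if (length(i) == 0L) stop_usage(sprintf("unknown flag id '%s'", flag_id))
  if (any(flags$active[i])) {
    flags$active[i] <- FALSE
    flags$comment[i] <- comment
  }
  flags
}

#' Levey-Jennings series for one metric
#'
#' Orders runs by acquisition date (ties broken by run id) and attaches, per
#' run, the applicable guide-set bands and flag status. Each lot scope uses
#' its own guide set, so band regimes change at lot boundaries. Runs lacking
#' the metric are emitted with an absent value.
#'
#' @param metrics [run_metrics()] rows for one analyte and titration across
#'   runs.
#' @param guide_sets List of `xmap_guide_set` objects (one per lot scope).
#' @param metric Metric name.
#' @return Plot-ready tibble: run, date, value, `mu`, `sigma`, band bounds
#'   at 1/2/3 SD, and `flagged`.
#' @export
levey_jennings_series <- function(metrics, guide_sets, metric) {
  if (!metric %in% CROSSRUN_METRICS) stop_usage(sprintf("unknown metric '%s'", metric))
  ord <- order(metrics$acquisition_date, metrics$run_id)
  mm <- metrics[ord, , drop = FALSE]
  find_gs <- function(row) {
    for (gs in guide_sets) {
      if (gs$analyte == row$analyte && gs$titration == row$titration &&
          same_lot_scope(lot_scope_of(row), gs$lot_scope)) return(gs)
    }
    NULL
  }
  rows <- lapply(seq_len(nrow(mm)), function(i) {
    row <- mm[i, , drop = FALSE]
    gs <- find_gs(row)
    v <- row[[metric]]
    mu <- sigma <- NA_real_
    flagged <- FALSE
    if (!is.null(gs)) {
      st <- gs$stats[gs$stats$metric == metric, ]
      mu <- st$mu; sigma <- st$sigma
      if (is.finite(v) && is.finite(sigma) && !(row$run_id %in% gs$members)) {
        flagged <- v < mu - 3 * sigma || v > mu + 3 * sigma
      }
    }
    tibble::tibble(run_id = row$run_id, acquisition_date = row$acquisition_date,
                   reagent_lot = row$reagent_lot, value = v, mu = mu,
                   sigma = sigma,
                   lower1 = mu - sigma, upper1 = mu + sigma,
                   lower2 = mu - 2 * sigma, upper2 = mu + 2 * sigma,
                   lower3 = mu - 3 * sigma, upper3 = mu + 3 * sigma,
                   flagged = flagged)
  })
  out <- dplyr::bind_rows(rows)
  out$metric <- metric
  out
}
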