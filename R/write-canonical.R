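# Canonical tidy outputs: one well-level CSV, one curve-parameter CSV and
# one titration-metric CSV per run, plus a JSON run manifest. Column order
# is fixed; identical inputs produce byte-identical files.

WELL_CSV_COLS <- c("run", "analyte", "bead_number", "sample_role", "sample_index",
                   "sample_id", "description", "well", "row_kind", "dilution",
                   "expected_conc", "fi_raw", "fi_blank_sub", "fi_bkgd_sub",
                   "fi_converted", "response_used", "norm_steps", "pct_cv",
                   "flag_high_cv", "excluded", "bead_count", "source_file")

CURVE_CSV_COLS <- c("run", "analyte", "titration", "model", "a_min", "a_max",
                    "m", "h", "s", "weight_exponent", "log_transformed",
                    "converged", "wrss", "ec50")

METRIC_CSV_COLS <- c("run", "analyte", "titration", "ec50_4pl", "ec50_5pl",
                     "auc", "high_mfi")

write_csv_stable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
            fileEncoding = "UTF-8", eol = "\n")
}

curve_param_table <- function(analysis) {
  run_name <- analysis$run$metadata$run_name
  rows <- list()
  for (a in names(analysis$by_analyte)) {
    fits <- analysis$by_analyte[[a]]$fits
    for (titr in names(fits)) {
      for (model in names(fits[[titr]])) {
        f <- fits[[titr]][[model]]
        p <- f$params
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run = run_name, analyte = a, titration = titr, model = model,
          a_min = if (is.null(p)) NA_real_ else p$a_min,
          a_max = if (is.null(p)) NA_real_ else p$a_max,
          m = if (is.null(p)) NA_real_ else p$m,
          h = if (is.null(p)) NA_real_ else p$h,
          s = if (is.null(p)) NA_real_ else p$s,
          weight_exponent = f$weight_exponent,
          log_transformed = f$log_transformed,
          converged = f$converged, wrss = f$wrss, ec50 = f$ec50
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::as_tibble(setNames(
      lapply(CURVE_CSV_COLS, function(x) logical(0)), CURVE_CSV_COLS))
  }
  out
}

#' Write canonical analysis outputs
#'
#' Emits three CSV files into `dir`: `wells.csv` (one row per well record
#' with normalization columns, %CV, flag and exclusion status),
#' `curves.csv` (one row per analyte x titration x model with fitted
#' parameters) and `metrics.csv` (one row per analyte x titration with 4pl
#' EC50, 5pl EC50, AUC and HighMFI; rows are present even when every well
#' of an analyte is excluded, with empty metric cells). Re-running on
#' identical input produces byte-identical files.
#'
#' @param analysis An `xmap_analysis`.
#' @param dir Output directory (created if needed).
#' @param manifest Also write `manifest.json` with run metadata and file
#'   provenance.
#' @return Invisibly, the paths written.
#' @export
write_canonical <- function(analysis, dir, manifest = FALSE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory '%s'", dir))
  }
  if (file.access(dir, 2L) != 0L) stop_io(sprintf("output directory '%s' is not writable", dir))
  run_name <- analysis$run$metadata$run_name

  w <- analysis$wells
  w$run <- run_name
  for (cn in setdiff(WELL_CSV_COLS, names(w))) w[[cn]] <- NA
  wells_path <- file.path(dir, "wells.csv")
  write_csv_stable(as.data.frame(w[, WELL_CSV_COLS]), wells_path)

  curves_path <- file.path(dir, "curves.csv")
  write_csv_stable(as.data.frame(curve_param_table(analysis)[, CURVE_CSV_COLS]),
                   curves_path)

  m <- analysis$metrics
  m$run <- run_name
  metrics_path <- file.path(dir, "metrics.csv")
  write_csv_stable(as.data.frame(m[, METRIC_CSV_COLS]), metrics_path)

  paths <- c(wells_path, curves_path, metrics_path)
  if (manifest) {
    man_path <- file.path(dir, "manifest.json")
    md <- analysis$run$metadata
    jsonlite::write_json(
      list(run = md[setdiff(names(md), "extra")], extra = md$extra,
           source_files = analysis$run$source_files,
           analytes = analysis$run$analytes,
           n_exclusions = length(analysis$exclusions)),
      man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, man_path)
  }
  invisible(paths)
}
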