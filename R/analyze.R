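# The per-run analysis pipeline: normalization, replicate groups, %CV
# flags, titration curve fits and metrics, interpolation of unknowns, and
# exclusion handling with targeted recomputation.
#
# Analytes are computed independently (the blank-bead channel is the one
# shared input), so an exclusion only forces recomputation of the analytes
# it touches; full and incremental analysis agree exactly.

#' Assay analysis options
#'
#' @param norm [norm_options()] controlling FI normalization.
#' @param weight_exponent Power `p` of the `1/response^p` fit weights
#'   (default 1.8).
#' @param models Curve models to fit per titration.
#' @param interp_model Model whose standard-curve fit is used to interpolate
#'   unknown concentrations.
#' @param cv_fi_gate,cv_limit_unknown,cv_limit_titration High-CV flag rule
#'   constants (defaults 100, 15, 20).
#' @param positivity Optional positivity parameters: a list with `baseline`
#'   (data frame `description`, `analyte`, `baseline`), `threshold` (data
#'   frame `analyte`, `threshold`) and `fold_change`.
#' @param fit_seed Seed for the fit's jittered restarts.
#' @return An object of class `xmap_options`.
#' @export
xmap_options <- function(norm = norm_options(), weight_exponent = 1.8,
                         models = c("fourpl", "fivepl"),
                         interp_model = "fourpl",
                         cv_fi_gate = 100, cv_limit_unknown = 15,
                         cv_limit_titration = 20, positivity = NULL,
                         fit_seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (!interp_model %in% models) {
    stop_config("`interp_model` must be one of the fitted `models`")
  }
  structure(list(norm = norm, weight_exponent = weight_exponent,
                 models = models, interp_model = interp_model,
                 cv_fi_gate = cv_fi_gate, cv_limit_unknown = cv_limit_unknown,
                 cv_limit_titration = cv_limit_titration,
                 positivity = positivity, fit_seed = as.integer(fit_seed)),
            class = "xmap_options")
}

titration_name_for_role <- function(role) {
  switch(role, standard = "Standard", qc_control = "QC", NA_character_)
}

# Analyze one analyte. Returns the per-analyte slice of every output table.
compute_analyte <- function(run, options, exclusions, analyte) {
  wells <- run$wells[run$wells$analyte == analyte, , drop = FALSE]
  wells$excluded <- FALSE
  for (ex in exclusions) {
    wells$excluded <- wells$excluded | exclusion_matches(wells, ex)
  }

  blank_wells <- NULL
  opts <- options$norm
  if (opts$subtract_blank_bead && !identical(analyte, opts$blank_bead_analyte)) {
    blank_wells <- run$wells[run$wells$analyte == opts$blank_bead_analyte, , drop = FALSE]
    if (nrow(blank_wells) == 0L) {
      stop_config(sprintf("blank-bead analyte '%s' not found in run", opts$blank_bead_analyte))
    }
  } else if (opts$subtract_blank_bead) {
    # the blank channel itself is not blank-subtracted
    opts$subtract_blank_bead <- FALSE
  }
  if (opts$subtract_background) {
    bg <- wells[wells$sample_role == "background" & !wells$excluded, , drop = FALSE]
    if (nrow(bg) == 0L) stop_domain(sprintf("no usable background wells for analyte '%s'", analyte))
  }
  wells <- prepare_response(wells, opts, blank_wells = blank_wells)

  # replicate groups: sample/dilution within the analyte. Raw rows get a
  # computed %CV; summary rows carry the file's reported %CV.
  grp <- dplyr::group_by(wells, .data$sample_id, .data$description,
                         .data$dilution, .data$sample_role, .data$row_kind)
  groups <- dplyr::summarise(
    grp,
    n_wells = dplyr::n(),
    wells_list = paste(.data$well, collapse = ","),
    expected_conc = .data$expected_conc[1],
    mean_fi = mean(.data$fi_analysis),
    mean_response = mean(.data$response_used),
    mean_fi_converted = mean(.data$fi_converted),
    reported_pct_cv = .data$reported_pct_cv[1],
    excluded = all(.data$excluded),
    .groups = "drop"
  )
  groups$analyte <- analyte
  groups$pct_cv <- NA_real_
  for (i in seq_len(nrow(groups))) {
    if (groups$row_kind[i] == "raw") {
      members <- wells$fi_analysis[wells$sample_id == groups$sample_id[i] &
                                     (is.na(wells$description) |
                                        wells$description %in% groups$description[i]) &
                                     wells$dilution == groups$dilution[i] &
                                     wells$row_kind == "raw"]
      if (length(members) >= 2L) groups$pct_cv[i] <- percent_cv(members)
    } else {
      groups$pct_cv[i] <- groups$reported_pct_cv[i]
    }
  }
  groups$flag_high_cv <- mapply(flag_high_cv, groups$mean_fi, groups$pct_cv,
                                groups$sample_role,
                                MoreArgs = list(fi_gate = options$cv_fi_gate,
                                                limit_unknown = options$cv_limit_unknown,
                                                limit_titration = options$cv_limit_titration))

  # propagate group %CV and flags back onto well rows
  key <- function(df) paste(df$sample_id, df$description, df$dilution, df$row_kind, sep = "\r")
  gmap <- match(key(wells), key(groups))
  wells$pct_cv <- groups$pct_cv[gmap]
  wells$flag_high_cv <- groups$flag_high_cv[gmap]

  # titration points (standards, and QC controls with expected conc)
  tg <- groups[groups$sample_role %in% c("standard", "qc_control") &
                 !is.na(groups$expected_conc), , drop = FALSE]
  # prefer raw rows when both table kinds are present
  if (nrow(tg) > 0L && any(tg$row_kind == "raw")) tg <- tg[tg$row_kind == "raw", , drop = FALSE]
  points <- tibble::tibble(
    analyte = analyte,
    titration = vapply(tg$sample_role, titration_name_for_role, character(1)),
    role = tg$sample_role, dose = tg$expected_conc,
    mean_response = tg$mean_response, mean_fi_converted = tg$mean_fi_converted,
    n_wells = tg$n_wells, excluded = tg$excluded
  )
  points <- points[order(points$titration, points$dose), , drop = FALSE]

  fits <- list()
  metric_rows <- list()
  for (titr in unique(points$titration)) {
    pts <- points[points$titration == titr, , drop = FALSE]
    fit_list <- list()
    for (model in options$models) {
      fit <- tryCatch(
        fit_titration(pts, model = model,
                      weight_exponent = options$weight_exponent,
                      log_transformed = options$norm$log_transform,
                      seed = options$fit_seed),
        xmapqc_fit_error = function(e) {
          structure(list(model = model, params = NULL,
                         weight_exponent = options$weight_exponent,
                         log_transformed = options$norm$log_transform,
                         converged = FALSE, wrss = NA_real_, ec50 = NA_real_,
                         n_points = sum(!pts$excluded)),
                    class = "curve_fit")
        })
      fit_list[[model]] <- fit
    }
    fits[[titr]] <- fit_list
    hm_pts <- tibble::tibble(mean_response = pts$mean_fi_converted,
                             excluded = pts$excluded)
    metric_rows[[titr]] <- tibble::tibble(
      analyte = analyte, titration = titr,
      ec50_4pl = if (!is.null(fit_list$fourpl)) fit_list$fourpl$ec50 else NA_real_,
      ec50_5pl = if (!is.null(fit_list$fivepl)) fit_list$fivepl$ec50 else NA_real_,
      auc = auc_trapezoid(pts),
      high_mfi = high_mfi(hm_pts)
    )
  }
  metrics <- dplyr::bind_rows(metric_rows)
  if (nrow(metrics) == 0L) {
    metrics <- tibble::tibble(analyte = character(), titration = character(),
                              ec50_4pl = double(), ec50_5pl = double(),
                              auc = double(), high_mfi = double())
  }

  # interpolate unknown concentrations from the standard fit
  interp <- tibble::tibble(analyte = character(), sample_id = character(),
                           description = character(), dilution = double(),
                           response = double(), conc = double(),
                           status = character())
  std_fit <- fits[["Standard"]][[options$interp_model]]
  ug <- groups[groups$sample_role == "unknown" & !groups$excluded, , drop = FALSE]
  if (nrow(ug) > 0L) {
    if (!is.null(std_fit) && isTRUE(std_fit$converged)) {
      res <- interpolate_concentration(std_fit, ug$mean_response, ug$dilution)
      interp <- tibble::tibble(analyte = analyte, sample_id = ug$sample_id,
                               description = ug$description, dilution = ug$dilution,
                               response = res$response, conc = res$conc,
                               status = res$status)
    } else {
      interp <- tibble::tibble(analyte = analyte, sample_id = ug$sample_id,
                               description = ug$description, dilution = ug$dilution,
                               response = ug$mean_response, conc = NA_real_,
                               status = "no_standard_fit")
    }
  }

  # optional positivity calls on unknown replicate groups (mean FI scale)
  if (!is.null(options$positivity) && nrow(ug) > 0L) {
    pp <- options$positivity
    fold <- pp$fold_change %||% 3
    calls <- rep(NA, nrow(ug))
    for (i in seq_len(nrow(ug))) {
      b <- pp$baseline$baseline[pp$baseline$description == ug$description[i] &
                                  pp$baseline$analyte == analyte]
      th <- pp$threshold$threshold[pp$threshold$analyte == analyte]
      calls[i] <- if (length(b) == 1L && length(th) == 1L) {
        positivity_call(ug$mean_fi[i], b, th, fold)
      } else {
        warn(sprintf("missing positivity baseline/threshold for %s/%s",
                     ug$description[i], analyte))
        NA
      }
    }
    interp$positive <- calls
  }

  list(wells = wells, groups = groups, points = points, fits = fits,
       metrics = metrics, interp = interp)
}

assemble_analysis <- function(run, options, exclusions, by_analyte) {
  ord <- run$analytes
  structure(list(
    run = run, options = options, exclusions = exclusions,
    by_analyte = by_analyte,
    wells = dplyr::bind_rows(lapply(ord, function(a) by_analyte[[a]]$wells)),
    groups = dplyr::bind_rows(lapply(ord, function(a) by_analyte[[a]]$groups)),
    points = dplyr::bind_rows(lapply(ord, function(a) by_analyte[[a]]$points)),
    metrics = dplyr::bind_rows(lapply(ord, function(a) by_analyte[[a]]$metrics)),
    interp = dplyr::bind_rows(lapply(ord, function(a) by_analyte[[a]]$interp))
  ), class = "xmap_analysis")
}

#' Analyze a run
#'
#' Runs the full per-run pipeline: normalization, replicate grouping and
#' %CV flagging, weighted 4pl/5pl titration fits with EC50/AUC/HighMFI,
#' and interpolation of unknowns from the assigned standard curve.
#' Exclusions supplied up front are equivalent to applying them afterwards
#' with [apply_exclusion()].
#'
#' @param run An `xmap_run` from [parse_workbook()] / [merge_run_files()].
#' @param options [xmap_options()].
#' @param exclusions List of [exclusion()] records already decided.
#' @return An `xmap_analysis` object with tibbles `wells`, `groups`,
#'   `points`, `metrics`, `interp` and per-analyte fit objects.
#' @export
analyze_run <- function(run, options = xmap_options(), exclusions = list()) {
  if (!inherits(run, "xmap_run")) stop_usage("`run` must be an `xmap_run`")
  by_analyte <- list()
  for (a in run$analytes) {
    by_analyte[[a]] <- compute_analyte(run, options, exclusions, a)
  }
  assemble_analysis(run, options, exclusions, by_analyte)
}

#' @export
print.xmap_analysis <- function(x, ...) {
  cat(sprintf("<xmap_analysis> %d analyte(s), %d well(s), %d titration metric row(s), %d exclusion(s)\n",
              length(x$run$analytes), nrow(x$wells), nrow(x$metrics),
              length(x$exclusions)))
  invisible(x)
}

#' Apply an exclusion and recompute affected results
#'
#' Marks the targeted wells as excluded (the rows are retained in every
#' output) and recomputes curve fits, metrics and interpolations for every
#' titration that contained an excluded point. Re-applying an identical
#' exclusion is a no-op.
#'
#' @param analysis An `xmap_analysis`.
#' @param excl An [exclusion()].
#' @return A list with `analysis` (the updated state) and `recompute`, a
#'   tibble of the (analyte, titration) pairs whose curves were refitted.
#' @export
apply_exclusion <- function(analysis, excl) {
  if (!inherits(analysis, "xmap_analysis")) stop_usage("`analysis` must be an `xmap_analysis`")
  if (!inherits(excl, "xmap_exclusion")) stop_usage("`excl` must be an `exclusion()`")
  run <- analysis$run
  hit <- exclusion_matches(run$wells, excl)
  if (!any(hit)) stop_usage("exclusion matches no wells in the run")

  same_target <- function(a, b) {
    identical(a$scope, b$scope) && identical(a$analyte, b$analyte) &&
      identical(a$sample_id, b$sample_id) &&
      identical(a$description, b$description) && identical(a$dilution, b$dilution)
  }
  if (any(vapply(analysis$exclusions, same_target, logical(1), excl))) {
    # duplicate exclusion: idempotent no-op
    return(list(analysis = analysis,
                recompute = tibble::tibble(analyte = character(), titration = character())))
  }
  exclusions <- c(analysis$exclusions, list(excl))

  # affected analytes: the target, plus everyone if the blank channel moved
  affected <- excl$analyte
  nopts <- analysis$options$norm
  if (nopts$subtract_blank_bead && identical(excl$analyte, nopts$blank_bead_analyte)) {
    affected <- run$analytes
  }

  # recompute set: titrations that contained a newly excluded point
  rec <- list()
  for (a in affected) {
    tpts <- analysis$by_analyte[[a]]$points
    if (a == excl$analyte && excl$scope == "analyte") {
      tit <- unique(tpts$titration)
    } else if (a == excl$analyte) {
      # replicate-group exclusions hit a titration only if the group is a
      # titration point
      sel <- analysis$groups$analyte == a &
        analysis$groups$sample_id == excl$sample_id &
        analysis$groups$sample_role %in% c("standard", "qc_control") &
        !is.na(analysis$groups$expected_conc)
      if (!is.null(excl$dilution)) sel <- sel & analysis$groups$dilution == excl$dilution
      tit <- unique(vapply(analysis$groups$sample_role[sel],
                           titration_name_for_role, character(1)))
    } else {
      tit <- unique(tpts$titration)
    }
    tit <- tit[!is.na(tit)]
    if (length(tit)) rec[[length(rec) + 1L]] <- tibble::tibble(analyte = a, titration = tit)
  }
  recompute <- if (length(rec)) dplyr::bind_rows(rec) else {
    tibble::tibble(analyte = character(), titration = character())
  }

  by_analyte <- analysis$by_analyte
  for (a in affected) {
    by_analyte[[a]] <- compute_analyte(run, analysis$options, exclusions, a)
  }
  list(analysis = assemble_analysis(run, analysis$options, exclusions, by_analyte),
       recompute = recompute)
}

#' Per-run titration metrics for cross-run QC
#'
#' Extracts one row per (analyte, titration) with the four cross-run QC
#' metrics (4pl EC50, 5pl EC50, AUC, HighMFI) and the run's lot scope
#' (reagent lot, isotype, conjugate).
#'
#' @param analysis An `xmap_analysis`.
#' @param run_id Identifier for the run (defaults to the run name).
#' @return A tibble suitable for [build_guide_set()] and
#'   [levey_jennings_series()].
#' @export
run_metrics <- function(analysis, run_id = NULL) {
  md <- analysis$run$metadata
  m <- analysis$metrics
  tibble::tibble(
    run_id = run_id %||% md$run_name,
    acquisition_date = md$acquisition_date,
    analyte = m$analyte, titration = m$titration,
    ec50_4pl = m$ec50_4pl, ec50_5pl = m$ec50_5pl,
    auc = m$auc, high_mfi = m$high_mfi,
    reagent_lot = md$reagent_lot, isotype = md$isotype, conjugate = md$conjugate
  )
}
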