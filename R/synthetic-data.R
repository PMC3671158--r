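# Synthetic instrument workbooks with known ground truth.
#
# The generator emulates the workbook dialect read by parse_workbook():
# one sheet per analyte, header metadata, a raw per-well table (optionally
# preceded by a summary table), and a short footer. Standard titrations are
# drawn from known logistic curves with multiplicative lognormal replicate
# noise, so every downstream stage can be tested against exact truth.

#' Configuration for a synthetic run
#'
#' Defaults describe a typical multiplexed binding-antibody run: a 10-point
#' 3-fold standard dilution series in triplicate, a handful of unknowns,
#' buffer-only background wells, and 5% multiplicative replicate noise.
#'
#' @param analytes List of analytes, each a list with `name`, `bead_number`
#'   and `params` (a [logistic_params()] giving the true standard curve).
#' @param standard_top_conc Concentration of the top standard (S1), in the
#'   assay's concentration units.
#' @param standard_dilutions Strictly increasing fold-dilutions of the
#'   standard; concentration of point k is `standard_top_conc /
#'   standard_dilutions[k]`.
#' @param n_replicates Wells per sample point.
#' @param unknowns List of unknowns, each `list(id, conc, dilution)` with the
#'   true (undiluted) sample concentration and its fold dilution.
#' @param qc_titration If `TRUE`, a quality-control titration (type codes
#'   `C1..Ck`) is generated at the standard concentrations scaled by
#'   `qc_scale`.
#' @param qc_scale Concentration scale factor of the QC titration relative
#'   to the standard.
#' @param background_fi_mean Mean FI of buffer-only background wells.
#' @param n_background Number of background wells per analyte.
#' @param blank_bead If `TRUE`, an additional uncoupled-bead sheet named
#'   `blank_bead_name` is written whose FI is background-only (no dose
#'   dependence).
#' @param blank_bead_name Sheet/analyte name of the blank-bead channel.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (unit median); 0 gives noiseless curves.
#' @param include_summary Also write a summary (per-sample) table above the
#'   raw table, with replicate-averaged FI and %CV.
#' @param run_name,reagent_lot,isotype,conjugate,acquisition_date Header
#'   metadata written into every sheet.
#' @param seed Integer seed; the same configuration and seed always produce
#'   a byte-identical workbook.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(analytes = list(
                           list(name = "ENV1", bead_number = 34,
                                params = logistic_params(50, 30000, m = 120, h = 1)),
                           list(name = "ENV2", bead_number = 35,
                                params = logistic_params(40, 25000, m = 80, h = 1.2))
                         ),
                         standard_top_conc = 10000,
                         standard_dilutions = 3^(0:9),
                         n_replicates = 3L,
                         unknowns = list(
                           list(id = "U1", conc = 500, dilution = 100),
                           list(id = "U2", conc = 2000, dilution = 100)
                         ),
                         qc_titration = FALSE, qc_scale = 0.5,
                         background_fi_mean = 25, n_background = 3L,
                         blank_bead = FALSE, blank_bead_name = "Blank",
                         noise_cv = 0.05, include_summary = FALSE,
                         run_name = "synthetic run", reagent_lot = "Lot-1",
                         isotype = "IgA", conjugate = "PE",
                         acquisition_date = "2012-03-01", seed = 1L) {
  if (length(analytes) < 1L) stop_config("at least one analyte is required")
  if (any(diff(standard_dilutions) <= 0)) {
    stop_config("`standard_dilutions` must be strictly increasing")
  }
  if (n_replicates < 1L) stop_config("`n_replicates` must be >= 1")
  if (noise_cv < 0) stop_config("`noise_cv` must be >= 0")
  if (background_fi_mean < 0) stop_config("`background_fi_mean` must be >= 0")
  structure(list(analytes = analytes, standard_top_conc = standard_top_conc,
                 standard_dilutions = standard_dilutions,
                 n_replicates = as.integer(n_replicates), unknowns = unknowns,
                 qc_titration = isTRUE(qc_titration), qc_scale = qc_scale,
                 background_fi_mean = background_fi_mean,
                 n_background = as.integer(n_background),
                 blank_bead = isTRUE(blank_bead), blank_bead_name = blank_bead_name,
                 noise_cv = noise_cv, include_summary = isTRUE(include_summary),
                 run_name = run_name, reagent_lot = reagent_lot,
                 isotype = isotype, conjugate = conjugate,
                 acquisition_date = acquisition_date, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate one well's fluorescence intensity
#'
#' The realized FI is the logistic curve value times a lognormal factor with
#' unit median and coefficient of variation `noise_cv` (so FI stays positive
#' and its spread grows with the signal, matching the heteroscedasticity
#' that motivates power-law fit weights). With `noise_cv = 0` the exact
#' curve value is returned.
#'
#' @param params True [logistic_params()] of the analyte.
#' @param conc Positive concentration.
#' @param noise_cv Replicate noise CV (fraction).
#' @return Realized FI (draws from the current RNG state when `noise_cv > 0`).
#' @export
simulate_well_fi <- function(params, conc, noise_cv = 0) {
  if (!is_scalar_number(conc) || conc <= 0) stop_domain("`conc` must be positive")
  mu <- eval_logistic(params, conc)
  if (noise_cv == 0) return(mu)
  sigma <- sqrt(log(1 + noise_cv^2))
  mu * rlnorm(1L, meanlog = 0, sdlog = sigma)
}

# background wells: normal around the configured mean with 10% CV,
# truncated at zero
draw_background <- function(n, mean_fi) {
  pmax(rnorm(n, mean_fi, 0.1 * mean_fi), 0)
}

#' Generate a synthetic run workbook with ground truth
#'
#' Writes a workbook in the instrument dialect (one raw table per analyte
#' sheet; optional summary table; optional blank-bead sheet) plus a
#' ground-truth JSON sidecar (`<path>.truth.json`). The same configuration
#' and seed produce a byte-identical workbook.
#'
#' @param config A [synth_config()].
#' @param path Output `.xlsx` path.
#' @return Invisibly, a list with `path`, `truth_path` and the `truth`
#'   object: per-analyte true curve parameters and a per-well table of
#'   noiseless and realized FI.
#' @export
generate_run_workbook <- function(config, path) {
  if (!inherits(config, "synth_config")) stop_config("`config` must be a `synth_config`")
  cfg <- config
  std_conc <- cfg$standard_top_conc / cfg$standard_dilutions

  withr::with_seed(cfg$seed, {
    sheets <- list()
    truth_rows <- list()
    # layout is identical across sheets (same plate, different bead regions)
    n_points <- length(std_conc) + (if (cfg$qc_titration) length(std_conc) else 0L) +
      length(cfg$unknowns)
    n_wells_total <- n_points * cfg$n_replicates + cfg$n_background

    plan <- list()
    widx <- 0L
    add_sample <- function(plan, type, desc, conc, dilution, exp_conc) {
      for (r in seq_len(cfg$n_replicates)) {
        widx <<- widx + 1L
        plan[[length(plan) + 1L]] <- list(type = type, desc = desc, conc = conc,
                                          dilution = dilution, exp_conc = exp_conc,
                                          well = well_label(widx))
      }
      plan
    }
    for (k in seq_along(std_conc)) {
      plan <- add_sample(plan, sprintf("S%d", k), "Standard", std_conc[k],
                         cfg$standard_dilutions[k], std_conc[k])
    }
    if (cfg$qc_titration) {
      for (k in seq_along(std_conc)) {
        plan <- add_sample(plan, sprintf("C%d", k), "QC", std_conc[k] * cfg$qc_scale,
                           cfg$standard_dilutions[k], std_conc[k] * cfg$qc_scale)
      }
    }
    for (i in seq_along(cfg$unknowns)) {
      u <- cfg$unknowns[[i]]
      plan <- add_sample(plan, sprintf("X%d", i), u$id, u$conc / u$dilution,
                         u$dilution, NA_real_)
    }
    for (b in seq_len(cfg$n_background)) {
      widx <- widx + 1L
      plan[[length(plan) + 1L]] <- list(type = "B", desc = "Background",
                                        conc = NA_real_, dilution = 1,
                                        exp_conc = NA_real_, well = well_label(widx))
    }
    stopifnot(length(plan) == n_wells_total)

    sheet_names <- vapply(cfg$analytes, function(a) {
      if (is.na(a$bead_number %||% NA)) a$name else sprintf("%s (%d)", a$name, a$bead_number)
    }, character(1))

    make_sheet <- function(analyte_name, params) {
      fis <- numeric(length(plan))
      fis_true <- numeric(length(plan))
      bg_draws <- draw_background(cfg$n_background, cfg$background_fi_mean)
      bgi <- 0L
      for (i in seq_along(plan)) {
        p <- plan[[i]]
        if (p$type == "B" || is.null(params)) {
          bgi <- bgi + 1L
          if (bgi > length(bg_draws)) {
            bg_draws <- c(bg_draws, draw_background(length(plan), cfg$background_fi_mean))
          }
          fis[i] <- bg_draws[bgi]
          fis_true[i] <- cfg$background_fi_mean
        } else {
          fis_true[i] <- eval_logistic(params, p$conc)
          fis[i] <- simulate_well_fi(params, p$conc, cfg$noise_cv)
        }
      }
      bg_mean <- mean(fis[vapply(plan, function(p) p$type == "B", logical(1))])

      header <- list(
        list("File Name", cfg$run_name),
        list("Acquisition Date", cfg$acquisition_date),
        list("Isotype", cfg$isotype),
        list("Conjugate", cfg$conjugate),
        list("Reagent Lot", cfg$reagent_lot),
        list(NA)
      )
      cells <- header
      if (cfg$include_summary) {
        cells[[length(cells) + 1L]] <-
          list("Type", "Wells", "Description", "FI", "FI - Bkgd", "%CV",
               "Exp Conc", "Dilution")
        types <- vapply(plan, function(p) p$type, character(1))
        for (tp in unique(types)) {
          idx <- which(types == tp)
          p <- plan[[idx[1]]]
          m <- mean(fis[idx])
          cv <- if (length(idx) >= 2L && m != 0) 100 * sd(fis[idx]) / m else NA_real_
          cells[[length(cells) + 1L]] <- list(
            tp, paste(vapply(plan[idx], function(q) q$well, character(1)), collapse = ","),
            p$desc, m, m - bg_mean, cv, p$exp_conc, p$dilution)
        }
        cells[[length(cells) + 1L]] <- list(NA)
      }
      cells[[length(cells) + 1L]] <-
        list("Type", "Well", "Description", "FI", "FI - Bkgd",
             "Exp Conc", "Dilution", "Bead Count")
      for (i in seq_along(plan)) {
        p <- plan[[i]]
        cells[[length(cells) + 1L]] <- list(p$type, p$well, p$desc, fis[i],
                                            fis[i] - bg_mean, p$exp_conc,
                                            p$dilution, 50)
      }
      cells[[length(cells) + 1L]] <- list(NA)
      cells[[length(cells) + 1L]] <- list(sprintf("Analysis of %s complete.", analyte_name))

      truth <- tibble::tibble(
        analyte = analyte_name,
        sample_id = vapply(plan, function(p) p$type, character(1)),
        description = vapply(plan, function(p) p$desc, character(1)),
        well = vapply(plan, function(p) p$well, character(1)),
        conc = vapply(plan, function(p) p$conc %||% NA_real_, double(1)),
        dilution = vapply(plan, function(p) p$dilution, double(1)),
        expected_conc = vapply(plan, function(p) p$exp_conc, double(1)),
        fi_true = fis_true, fi = fis
      )
      list(cells = cells, truth = truth)
    }

    for (ai in seq_along(cfg$analytes)) {
      a <- cfg$analytes[[ai]]
      sh <- make_sheet(a$name, a$params)
      sheets[[sheet_names[ai]]] <- sh$cells
      truth_rows[[length(truth_rows) + 1L]] <- sh$truth
    }
    if (cfg$blank_bead) {
      sh <- make_sheet(cfg$blank_bead_name, NULL)
      sheets[[cfg$blank_bead_name]] <- sh$cells
      truth_rows[[length(truth_rows) + 1L]] <- sh$truth
    }

    write_xlsx_minimal(sheets, path)

    truth <- list(
      config = list(seed = cfg$seed, noise_cv = cfg$noise_cv,
                    n_replicates = cfg$n_replicates,
                    standard_top_conc = cfg$standard_top_conc,
                    standard_dilutions = cfg$standard_dilutions),
      curves = lapply(cfg$analytes, function(a) {
        list(name = a$name, bead_number = a$bead_number %||% NA_integer_,
             params = unclass(a$params))
      }),
      unknowns = cfg$unknowns,
      wells = dplyr::bind_rows(truth_rows)
    )
    truth_path <- paste0(path, ".truth.json")
    jsonlite::write_json(truth, truth_path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(list(path = path, truth_path = truth_path, truth = truth))
  })
}
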