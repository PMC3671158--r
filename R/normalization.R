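# Normalization of raw fluorescence intensities into the response values
# used for curve fitting and interpolation.
#
# Pipeline order (each step optional except the conversion):
#   blank-bead subtraction -> background-well subtraction -> convert_fi
#   -> natural-log transform.
# Both subtractions are additive per well, so their order does not change
# the result; the order above is fixed for provenance reporting.

#' Normalization options
#'
#' @param subtract_blank_bead Subtract the same-well FI of an uncoupled
#'   ("blank") bead region, removing signal from non-specific binding to the
#'   beads themselves.
#' @param subtract_background Subtract the mean FI of buffer-only background
#'   wells, removing detector background.
#' @param log_transform Natural-log transform the converted FI before curve
#'   fitting (helps stabilize variance extremes).
#' @param blank_bead_analyte Name of the blank-bead analyte sheet; required
#'   when `subtract_blank_bead` is `TRUE`.
#'
#' @return An object of class `norm_options`.
#' @export
norm_options <- function(subtract_blank_bead = FALSE, subtract_background = FALSE,
                         log_transform = FALSE, blank_bead_analyte = NULL) {
  if (isTRUE(subtract_blank_bead) && is.null(blank_bead_analyte)) {
    stop_config("`blank_bead_analyte` is required when `subtract_blank_bead` is TRUE")
  }
  structure(list(subtract_blank_bead = isTRUE(subtract_blank_bead),
                 subtract_background = isTRUE(subtract_background),
                 log_transform = isTRUE(log_transform),
                 blank_bead_analyte = blank_bead_analyte),
            class = "norm_options")
}

#' Mean FI of background wells
#'
#' Excluded background wells (when an `excluded` column is present) do not
#' contribute.
#'
#' @param wells Well table (rows for one analyte) with `sample_role` and
#'   `fi` columns.
#' @return Arithmetic mean of the background wells' FI.
#' @export
background_mean <- function(wells) {
  keep <- wells$sample_role == "background"
  if ("excluded" %in% names(wells)) keep <- keep & !wells$excluded
  bg <- wells$fi[keep]
  if (length(bg) == 0L) {
    stop_domain("no background wells available for background subtraction")
  }
  mean(bg)
}

#' Subtract same-well blank-bead FI
#'
#' For raw rows the blank-bead FI measured in the same well position is
#' subtracted; for summary rows the blank sheet's row with the same well set
#' is used. Results may be negative; the downstream conversion restores
#' positivity.
#'
#' @param wells Well table for the target analyte (columns `well`, `fi`,
#'   `row_kind`).
#' @param blank_wells Well table for the blank-bead analyte.
#' @return `wells` FI minus the positionally matched blank FI.
#' @export
subtract_blank_bead <- function(wells, blank_wells) {
  blank_fi <- setNames(blank_wells$fi, blank_wells$well)
  missing <- setdiff(wells$well, names(blank_fi))
  if (length(missing) > 0L) {
    stop_format(sprintf("blank-bead sheet is missing well(s): %s",
                        paste(missing, collapse = ", ")))
  }
  wells$fi - unname(blank_fi[wells$well])
}

#' Floor-and-shift FI conversion
#'
#' The mandatory conversion applied to normalized FI before curve fitting:
#' `max(FI, 0) + 1`. It absorbs negative values introduced by blank-bead or
#' background subtraction, and its output is always at least 1 so a
#' subsequent log transform is defined.
#'
#' @param fi Numeric vector of (possibly negative) normalized FI values.
#' @return `pmax(fi, 0) + 1`, elementwise.
#' @export
#' @examples
#' convert_fi(c(-50, 0, 250.5)) # 1, 1, 251.5
convert_fi <- function(fi) {
  pmax(fi, 0) + 1
}

#' Prepare response values for curve fitting
#'
#' Applies the configured normalization pipeline to a well table and records
#' per-step columns for provenance: `fi_raw`, `fi_blank_sub`, `fi_bkgd_sub`,
#' `fi_converted`, `response_used`, plus `fi_analysis` (the subtracted,
#' pre-conversion FI on which replicate %CVs are computed) and a
#' `norm_steps` string naming the steps applied.
#'
#' @param wells Well table for one analyte.
#' @param options A [norm_options()] object.
#' @param blank_wells Well table of the blank-bead analyte (required when
#'   blank subtraction is enabled).
#' @return `wells` with normalization columns appended.
#' @export
prepare_response <- function(wells, options = norm_options(), blank_wells = NULL) {
  steps <- character(0)
  wells$fi_raw <- wells$fi
  fi <- wells$fi

  if (options$subtract_blank_bead) {
    if (is.null(blank_wells)) stop_config("blank-bead subtraction requested but no blank-bead wells supplied")
    tmp <- wells
    tmp$fi <- fi
    fi <- subtract_blank_bead(tmp, blank_wells)
    steps <- c(steps, "blank_bead")
  }
  wells$fi_blank_sub <- fi

  if (options$subtract_background) {
    fi <- fi - background_mean(wells)
    steps <- c(steps, "background")
  }
  wells$fi_bkgd_sub <- fi
  wells$fi_analysis <- fi

  fi <- convert_fi(fi)
  steps <- c(steps, "convert")
  wells$fi_converted <- fi

  if (options$log_transform) {
    fi <- log(fi)
    steps <- c(steps, "log")
  }
  wells$response_used <- fi
  wells$norm_steps <- paste(steps, collapse = "+")
  wells
}
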