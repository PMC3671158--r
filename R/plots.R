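# Curve and QC visualizations. Plots are returned as ggplot objects and
# optionally written to PNG/PDF; tests compare the underlying data series,
# not file bytes.

curve_frame <- function(fit, dose_range, n = 200L) {
  doses <- exp(seq(log(dose_range[1]), log(dose_range[2]), length.out = n))
  tibble::tibble(dose = doses, response = eval_logistic(fit$params, doses))
}

save_plot <- function(p, path, width = 6, height = 4.5) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("output directory '%s' does not exist", dir))
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Plot a fitted titration curve with its source data
#'
#' Shows the fitted 4pl/5pl curve over the dose range spanned by the
#' observed points, overlaid with the replicate-group means used for the
#' fit. Excluded points are rendered with an open marker. A non-converged
#' fit yields a points-only plot with a warning annotation.
#'
#' @param fit A `curve_fit`.
#' @param points Titration points (`dose`, `mean_response`, optional
#'   `excluded`).
#' @param path Optional output file (`.png` or `.pdf`).
#' @param title Plot title.
#' @return The ggplot object, invisibly if written to `path`.
#' @export
plot_standard_curve <- function(fit, points, path = NULL, title = NULL) {
  pts <- tibble::as_tibble(as.data.frame(points))
  if (is.null(pts$excluded)) pts$excluded <- FALSE
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose, y = .data$mean_response)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose (concentration)", y = "Response (prepared FI)",
                  title = title %||% "Titration curve", shape = "Excluded") +
    ggplot2::theme_bw()
  if (isTRUE(fit$converged)) {
    cf <- curve_frame(fit, range(pts$dose[!pts$excluded]))
    p <- p + ggplot2::geom_line(data = cf,
                                ggplot2::aes(x = .data$dose, y = .data$response),
                                color = "steelblue")
  } else {
    p <- p + ggplot2::annotate("text", x = exp(mean(log(range(pts$dose)))),
                               y = mean(range(pts$mean_response)),
                               label = "curve fit did not converge",
                               color = "firebrick")
  }
  p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1))
  if (!is.null(path)) {
    save_plot(p, path)
    return(invisible(p))
  }
  p
}

#' Overlay standard curves from several runs
#'
#' The curve "graveyard": all runs' fitted curves for one analyte and
#' titration on shared axes, with panels for both FI and log(FI).
#'
#' @param fits Named list mapping run label to `curve_fit`; all fits must be
#'   for the same analyte (enforced via the `analyte` attribute when
#'   present, or the `analytes` argument).
#' @param analytes Optional character vector (one per fit) used to enforce
#'   that all curves describe the same analyte.
#' @param dose_range Dose range to draw (defaults to 1 to 1e4).
#' @param path Optional output file.
#' @return The ggplot object.
#' @export
plot_curve_overlay <- function(fits, analytes = NULL, dose_range = c(1, 1e4),
                               path = NULL) {
  if (length(fits) < 1L) stop_usage("at least one fit is required")
  if (is.null(names(fits))) names(fits) <- paste("run", seq_along(fits))
  if (!is.null(analytes) && length(unique(analytes)) > 1L) {
    stop_usage("all overlaid curves must describe the same analyte")
  }
  frames <- lapply(names(fits), function(lbl) {
    f <- fits[[lbl]]
    if (!isTRUE(f$converged)) return(NULL)
    cf <- curve_frame(f, dose_range)
    cf$run <- lbl
    cf
  })
  df <- dplyr::bind_rows(frames)
  if (nrow(df) == 0L) stop_fit("no converged fits to plot")
  df_log <- df
  df_log$response <- log10(pmax(df_log$response, 1e-12))
  df$panel <- "FI"
  df_log$panel <- "log10(FI)"
  all <- dplyr::bind_rows(df, df_log)
  p <- ggplot2::ggplot(all, ggplot2::aes(x = .data$dose, y = .data$response,
                                         color = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Dose (concentration)", y = "Response", color = "Run") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    save_plot(p, path, width = 8, height = 4)
    return(invisible(p))
  }
  p
}

#' Levey-Jennings plot for one metric
#'
#' Run-ordered metric values with the guide-set mean and +/- 1, 2, 3 SD
#' bands; flagged runs are highlighted. Band regimes change at lot
#' boundaries.
#'
#' @param series Output of [levey_jennings_series()].
#' @param path Optional output file.
#' @return The ggplot object.
#' @export
plot_levey_jennings <- function(series, path = NULL) {
  s <- series
  s$idx <- seq_len(nrow(s))
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$idx, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower3, ymax = .data$upper3),
                         fill = "grey85", alpha = 0.6) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower2, ymax = .data$upper2),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower1, ymax = .data$upper1),
                         fill = "grey65", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), linetype = 2, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 2, na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::scale_x_continuous(breaks = s$idx, labels = s$run_id) +
    ggplot2::labs(x = "Run (by acquisition date)", y = unique(s$metric),
                  color = "Flagged") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) {
    save_plot(p, path, width = 8, height = 4)
    return(invisible(p))
  }
  p
}
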