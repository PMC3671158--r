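# Dose-response curve fitting and titration metrics.
#
# The five-parameter logistic (5pl) in log dose is
#   f(x) = A_min + (A_max - A_min) / (1 + exp(-h * (ln x - ln m)))^s
# with inflection dose m > 0, slope h, and asymmetry s > 0. Fixing s = 1
# gives the four-parameter logistic (4pl). As dose -> 0 the curve
# approaches A_min when h > 0 (A_max when h < 0), and the other asymptote
# as dose -> Inf.

#' Logistic dose-response parameters
#'
#' Container for the parameters of the asymmetric (five-parameter) logistic
#' model in log dose. With asymmetry `s = 1` this is the familiar
#' four-parameter logistic.
#'
#' @param a_min Asymptote approached as dose tends to 0 (for positive slope).
#' @param a_max Asymptote approached as dose tends to infinity (for positive
#'   slope).
#' @param m Inflection dose; must be positive. For `s = 1` this equals the
#'   EC50.
#' @param h Slope in log dose; must be nonzero.
#' @param s Asymmetry; must be positive. `s = 1` gives the symmetric 4pl.
#'
#' @return An object of class `logistic_params`.
#' @export
#' @examples
#' p <- logistic_params(0, 100, m = 10, h = 1)
#' eval_logistic(p, 10) # midpoint: 50
logistic_params <- function(a_min, a_max, m, h, s = 1) {
  if (!is_scalar_number(m) || m <= 0) stop_domain("`m` (inflection dose) must be a positive number")
  if (!is_scalar_number(s) || s <= 0) stop_domain("`s` (asymmetry) must be a positive number")
  if (!is_scalar_number(h) || h == 0) stop_domain("`h` (slope) must be a nonzero number")
  if (!is_scalar_number(a_min) || !is_scalar_number(a_max)) {
    stop_domain("asymptotes `a_min`/`a_max` must be finite numbers")
  }
  structure(list(a_min = a_min, a_max = a_max, m = m, h = h, s = s),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> a_min=%g a_max=%g m=%g h=%g s=%g\n",
              x$a_min, x$a_max, x$m, x$h, x$s))
  invisible(x)
}

#' Evaluate a logistic dose-response curve
#'
#' @param params A [logistic_params()] object.
#' @param dose Vector of positive doses.
#'
#' @return Numeric vector of responses, one per dose.
#' @export
eval_logistic <- function(params, dose) {
  if (any(!is.finite(dose)) || any(dose <= 0)) stop_domain("all doses must be positive and finite")
  with(params, a_min + (a_max - a_min) / (1 + exp(-h * (log(dose) - log(m))))^s)
}

# Raw evaluator on an unconstrained parameter vector
# theta = (a_min, a_max, log m, h, log s); used by the optimizer.
eval_theta <- function(theta, log_dose, fix_s = FALSE) {
  s <- if (fix_s) 1 else exp(theta[5L])
  theta[1L] + (theta[2L] - theta[1L]) / (1 + exp(-theta[4L] * (log_dose - theta[3L])))^s
}

#' Fit a weighted 4pl/5pl curve to titration points
#'
#' Minimizes the weighted residual sum of squares
#' \eqn{\sum_i w_i (y_i - f(x_i))^2} with power-law weights
#' \eqn{w_i = 1/\max(y_i, 1)^p} over the non-excluded points, using
#' Levenberg-Marquardt least squares. Weights are computed from the
#' observed response (not the fitted value); the floor at 1 guards the
#' division for small or log-scale responses. The 4pl fit is the same
#' problem with the asymmetry pinned at 1.
#'
#' @param points Data frame with columns `dose` (positive), `mean_response`,
#'   and optionally `excluded` (logical; excluded points are ignored).
#' @param model `"fourpl"` or `"fivepl"`.
#' @param weight_exponent Nonnegative exponent `p` of the `1/response^p`
#'   weights. `p = 0` is ordinary least squares; the conventional default
#'   for bead-array titrations is 1.8.
#' @param log_transformed Flag recorded on the fit indicating the responses
#'   were natural-log transformed upstream (affects downstream reporting,
#'   not the optimization).
#' @param seed Integer seed used only for the jittered restarts attempted
#'   when the first optimization does not converge.
#'
#' @return An object of class `curve_fit`: model, fitted [logistic_params()],
#'   convergence status, weighted RSS, and the midpoint EC50 (see
#'   [ec50_from_params()]).
#' @export
fit_titration <- function(points, model = c("fourpl", "fivepl"),
                          weight_exponent = 1.8, log_transformed = FALSE,
                          seed = 1L) {
  model <- match.arg(model)
  if (!is_scalar_number(weight_exponent) || weight_exponent < 0) {
    stop_domain("`weight_exponent` must be a nonnegative number")
  }
  pts <- as.data.frame(points)
  if (!is.null(pts$excluded)) pts <- pts[!pts$excluded, , drop = FALSE]
  x <- pts$dose
  y <- pts$mean_response
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n_free <- if (model == "fourpl") 4L else 5L
  if (length(x) < n_free) {
    stop_fit(sprintf("fit is under-determined: %d usable points for a %d-parameter model",
                     length(x), n_free))
  }
  if (any(x <= 0)) stop_domain("all doses must be positive")

  lx <- log(x)
  w <- 1 / pmax(y, 1)^weight_exponent
  sw <- sqrt(w)
  fix_s <- model == "fourpl"

  resid_fn <- function(theta) sw * (y - eval_theta(theta, lx, fix_s = fix_s))

  # Initialization: asymptotes from the observed range, slope sign from the
  # observed monotone direction, m from the dose nearest the half-range
  # crossing, s = 1.
  dir_up <- stats::cor(lx, y) >= 0
  half <- (min(y) + max(y)) / 2
  m0 <- x[which.min(abs(y - half))]
  theta0 <- c(min(y), max(y), log(m0), if (dir_up) 1 else -1, 0)

  run_lm <- function(theta) {
    fit <- try(minpack.lm::nls.lm(
      par = theta, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  best <- run_lm(theta0)
  ok <- function(f) !is.null(f) && f$info %in% 1:4 && all(is.finite(f$par))
  if (!ok(best)) {
    withr::with_seed(seed, {
      for (k in 1:3) {
        jit <- theta0 + rnorm(5L, sd = c(abs(half) * 0.1 + 1, abs(half) * 0.1 + 1, 0.5, 0.3, 0.2))
        cand <- run_lm(jit)
        if (ok(cand) && (!ok(best) || cand$deviance < best$deviance)) best <- cand
      }
    })
  }

  converged <- ok(best)
  if (!converged) {
    return(structure(list(model = model, params = NULL,
                          weight_exponent = weight_exponent,
                          log_transformed = log_transformed,
                          converged = FALSE, wrss = NA_real_,
                          ec50 = NA_real_, n_points = length(x)),
                     class = "curve_fit"))
  }

  th <- best$par
  params <- logistic_params(th[1L], th[2L], exp(th[3L]), th[4L],
                            if (fix_s) 1 else exp(th[5L]))
  fit <- structure(list(model = model, params = params,
                        weight_exponent = weight_exponent,
                        log_transformed = log_transformed,
                        converged = TRUE, wrss = best$deviance,
                        ec50 = NA_real_, n_points = length(x)),
                   class = "curve_fit")
  fit$ec50 <- ec50_from_params(fit)
  fit
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> %s, converged=%s", x$model, x$converged))
  if (x$converged) {
    cat(sprintf(", wRSS=%.4g, EC50=%.6g (p=%g%s)", x$wrss, x$ec50,
                x$weight_exponent, if (x$log_transformed) ", log response" else ""))
  }
  cat("\n")
  if (x$converged) print(x$params)
  invisible(x)
}

#' Midpoint EC50 of a fitted curve
#'
#' The EC50 is the dose at which the curve reaches the midpoint between its
#' asymptotes. In closed form \eqn{x^* = m (2^{1/s} - 1)^{-1/h}}; for the
#' symmetric 4pl (`s = 1`) this collapses to the inflection dose `m`.
#'
#' @param fit A converged `curve_fit` (or a bare [logistic_params()]).
#' @return The EC50 dose, or `NA` if undefined (e.g. slope numerically 0).
#' @export
ec50_from_params <- function(fit) {
  p <- if (inherits(fit, "logistic_params")) fit else {
    if (!isTRUE(fit$converged)) return(NA_real_)
    fit$params
  }
  out <- p$m * (2^(1 / p$s) - 1)^(-1 / p$h)
  if (!is.finite(out) || out <= 0) NA_real_ else out
}

#' Trapezoidal area under a titration curve
#'
#' Applies the trapezoidal rule to (log10 dose, mean response) pairs sorted
#' by ascending dose, over the observed points only. Excluded points are
#' ignored.
#'
#' @param points Data frame with `dose`, `mean_response`, optional `excluded`.
#' @return The area, or `NA` when fewer than two distinct doses remain.
#' @export
auc_trapezoid <- function(points) {
  pts <- as.data.frame(points)
  if (!is.null(pts$excluded)) pts <- pts[!pts$excluded, , drop = FALSE]
  pts <- pts[is.finite(pts$dose) & is.finite(pts$mean_response), , drop = FALSE]
  if (length(unique(pts$dose)) < 2L) return(NA_real_)
  pts <- pts[order(pts$dose), , drop = FALSE]
  x <- log10(pts$dose)
  y <- pts$mean_response
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Highest mean fluorescence intensity of a titration
#'
#' Maximum replicate-group mean response over the non-excluded points.
#' Computed on the converted FI scale even when fitting used log responses.
#'
#' @param points Data frame with `mean_response`, optional `excluded`.
#' @return The maximum, or `NA` when every point is excluded.
#' @export
high_mfi <- function(points) {
  pts <- as.data.frame(points)
  if (!is.null(pts$excluded)) pts <- pts[!pts$excluded, , drop = FALSE]
  y <- pts$mean_response[is.finite(pts$mean_response)]
  if (length(y) == 0L) return(NA_real_)
  max(y)
}

#' Interpolate concentrations from a fitted standard curve
#'
#' Inverts the fitted logistic at each observed response. Responses outside
#' the open interval between the asymptotes are never extrapolated: they are
#' reported as out of range, with the side identified relative to the curve
#' (low = beyond the dose-to-zero asymptote, high = beyond the
#' dose-to-infinity asymptote). The interpolated dose is multiplied by the
#' sample's fold dilution to give the reported sample concentration.
#'
#' @param fit Converged `curve_fit` for the assigned standard titration.
#' @param y Vector of observed responses on the same prepared-response scale
#'   as the fit.
#' @param dilution Fold dilution(s) of the samples (scalar or one per `y`).
#'
#' @return A tibble with columns `response`, `conc` (NA when out of range)
#'   and `status` (`"ok"`, `"oor_low"`, `"oor_high"`).
#' @export
interpolate_concentration <- function(fit, y, dilution = 1) {
  if (!isTRUE(fit$converged)) stop_fit("cannot interpolate from a non-converged fit")
  p <- fit$params
  if (length(dilution) == 1L) dilution <- rep(dilution, length(y))
  if (length(dilution) != length(y)) stop_domain("`dilution` must be scalar or match `y`")
  if (any(dilution <= 0, na.rm = TRUE)) stop_domain("dilutions must be positive")

  f0 <- if (p$h > 0) p$a_min else p$a_max   # asymptote as dose -> 0
  finf <- if (p$h > 0) p$a_max else p$a_min # asymptote as dose -> Inf
  lo <- min(p$a_min, p$a_max)
  hi <- max(p$a_min, p$a_max)

  conc <- rep(NA_real_, length(y))
  status <- rep(NA_character_, length(y))
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= lo || yi >= hi) {
      # outside the open asymptote interval: identify the side
      if (!is.finite(yi)) {
        status[i] <- "oor_high"
      } else if ((yi - f0) * (finf - f0) <= 0) {
        status[i] <- "oor_low"
      } else {
        status[i] <- "oor_high"
      }
      next
    }
    r <- (p$a_max - p$a_min) / (yi - p$a_min)
    x <- p$m * (r^(1 / p$s) - 1)^(-1 / p$h)
    if (!is.finite(x) || x <= 0) {
      status[i] <- if ((yi - f0) * (finf - f0) <= 0) "oor_low" else "oor_high"
    } else {
      conc[i] <- x * dilution[i]
      status[i] <- "ok"
    }
  }
  tibble::tibble(response = y, conc = conc, status = status)
}
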