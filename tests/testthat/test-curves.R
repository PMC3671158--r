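test_that("logistic evaluation matches closed-form values", {
  p4 <- logistic_params(0, 100, m = 10, h = 1)
  expect_equal(eval_logistic(p4, 10), 50)
  expect_equal(eval_logistic(p4, 1e12), 100, tolerance = 1e-6)
  p5 <- logistic_params(0, 100, m = 10, h = 1, s = 2)
  expect_equal(eval_logistic(p5, 10), 25) # 100 / 2^2
  # monotone in dose for fixed slope sign
  doses <- 10^seq(-3, 5, length.out = 50)
  expect_true(all(diff(eval_logistic(p5, doses)) > 0))
  expect_error(eval_logistic(p4, -1), class = "xmapqc_domain_error")
})

test_that("EC50 closed form agrees with a root-finding oracle", {
  p4 <- logistic_params(0, 100, m = 250, h = 1.3)
  expect_equal(ec50_from_params(p4), 250)
  p5 <- logistic_params(0, 100, m = 100, h = 1, s = 2)
  expect_equal(ec50_from_params(p5), 100 / (sqrt(2) - 1), tolerance = 1e-9)
  # oracle: solve f(x) = midpoint numerically for assorted parameter sets
  cases <- list(
    logistic_params(50, 30000, m = 120, h = 0.8, s = 1.7),
    logistic_params(10, 5000, m = 42, h = 2.2, s = 0.4),
    logistic_params(200, 100, m = 7, h = 1.1, s = 3) # decreasing curve
  )
  for (p in cases) {
    mid <- (p$a_min + p$a_max) / 2
    root <- uniroot(function(x) eval_logistic(p, x) - mid,
                    lower = p$m * 1e-6, upper = p$m * 1e6, tol = 1e-12)$root
    expect_equal(ec50_from_params(p), root, tolerance = 1e-7)
  }
  # s = 1 collapses to m for any slope
  expect_equal(ec50_from_params(logistic_params(0, 1, m = 3.7, h = -2.5)), 3.7)
})

test_that("noiseless points are recovered to tight tolerance and 5pl nests 4pl", {
  truth <- logistic_params(0, 30000, m = 1000, h = 1)
  pts <- make_points(truth, noise_cv = 0)
  f4 <- fit_titration(pts, "fourpl", weight_exponent = 0)
  expect_true(f4$converged)
  expect_equal(f4$params$a_min, truth$a_min, tolerance = 1e-4)
  expect_equal(f4$params$a_max, truth$a_max, tolerance = 1e-4)
  expect_equal(f4$params$m, truth$m, tolerance = 1e-4)
  expect_equal(f4$params$h, truth$h, tolerance = 1e-4)
  expect_equal(f4$ec50, 1000, tolerance = 1e-4)

  f5 <- fit_titration(pts, "fivepl", weight_exponent = 0)
  expect_true(f5$converged)
  expect_equal(f5$params$s, 1, tolerance = 1e-3)
  expect_lte(f5$wrss, f4$wrss + 1e-8)
})

test_that("weighted fits recover parameters under noise and respect exclusions", {
  truth <- logistic_params(50, 30000, m = 120, h = 1)
  pts <- make_points(truth, noise_cv = 0.05, seed = 11)
  fit <- fit_titration(pts, "fourpl")
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 120) / 120, 0.25)

  # refit on (all minus one point) equals fit on the reduced set exactly
  pts2 <- pts
  pts2$excluded[4] <- TRUE
  f_marked <- fit_titration(pts2, "fourpl")
  f_reduced <- fit_titration(pts[-4, ], "fourpl")
  expect_identical(f_marked$params, f_reduced$params)
  expect_identical(f_marked$wrss, f_reduced$wrss)
})

test_that("under-determined fits raise a fit error", {
  truth <- logistic_params(0, 100, m = 10, h = 1)
  pts <- make_points(truth, doses = c(1, 10, 100))
  expect_error(fit_titration(pts, "fourpl"), class = "xmapqc_fit_error")
  pts4 <- make_points(truth, doses = c(1, 10, 100, 1000))
  expect_error(fit_titration(pts4, "fivepl"), class = "xmapqc_fit_error")
})

test_that("trapezoidal AUC matches hand-computed and oracle values", {
  flat <- tibble::tibble(dose = c(1, 10), mean_response = c(5, 5))
  expect_equal(auc_trapezoid(flat), 5)
  tri <- tibble::tibble(dose = c(1, 10, 100), mean_response = c(0, 10, 0))
  expect_equal(auc_trapezoid(tri), 10)
  expect_true(is.na(auc_trapezoid(tibble::tibble(dose = 1, mean_response = 3))))

  # dense-Riemann oracle on random point sets
  riemann <- function(pts, n = 2e5) {
    pts <- pts[order(pts$dose), ]
    x <- log10(pts$dose)
    grid <- seq(min(x), max(x), length.out = n)
    y <- approx(x, pts$mean_response, xout = grid)$y
    mean(y[-1] + y[-n]) / 2 * (max(x) - min(x))
  }
  withr::with_seed(42, {
    for (i in 1:10) {
      k <- sample(3:12, 1)
      pts <- tibble::tibble(dose = sort(10^runif(k, -1, 4)),
                            mean_response = runif(k, 0, 1000))
      expect_equal(auc_trapezoid(pts), riemann(pts), tolerance = 1e-6)
    }
  })
})

test_that("HighMFI is the maximum non-excluded mean response", {
  pts <- tibble::tibble(mean_response = c(120, 450, 390),
                        excluded = c(FALSE, FALSE, FALSE))
  expect_equal(high_mfi(pts), 450)
  pts$excluded[2] <- TRUE
  expect_equal(high_mfi(pts), 390)
  expect_equal(high_mfi(tibble::tibble(mean_response = 7)), 7)
  expect_true(is.na(high_mfi(tibble::tibble(mean_response = 1, excluded = TRUE))))
})

test_that("interpolation inverts the curve and never extrapolates", {
  p <- logistic_params(50, 30000, m = 120, h = 1.2, s = 1.5)
  fit <- structure(list(model = "fivepl", params = p, converged = TRUE),
                   class = "curve_fit")
  y <- eval_logistic(p, 37.5)
  expect_equal(interpolate_concentration(fit, y)$conc, 37.5, tolerance = 1e-9)
  # midpoint response maps to EC50, scaled by the fold dilution
  mid <- (p$a_min + p$a_max) / 2
  expect_equal(interpolate_concentration(fit, mid, dilution = 100)$conc,
               100 * ec50_from_params(p), tolerance = 1e-9)
  # outside the asymptotes: sided out-of-range markers, no value
  res_hi <- interpolate_concentration(fit, p$a_max + 5)
  expect_identical(res_hi$status, "oor_high")
  expect_true(is.na(res_hi$conc))
  res_lo <- interpolate_concentration(fit, p$a_min - 1)
  expect_identical(res_lo$status, "oor_low")
  # decreasing curve (high response at low dose): sides follow orientation
  pd <- logistic_params(9000, 30, m = 50, h = 1)
  fd <- structure(list(model = "fourpl", params = pd, converged = TRUE),
                  class = "curve_fit")
  expect_identical(interpolate_concentration(fd, 9500)$status, "oor_low")
  expect_identical(interpolate_concentration(fd, 10)$status, "oor_high")
})

test_that("interpolate after eval is the identity across the asymptote interior", {
  p <- logistic_params(50, 30000, m = 120, h = 1, s = 0.7)
  fit <- structure(list(model = "fivepl", params = p, converged = TRUE),
                   class = "curve_fit")
  withr::with_seed(3, {
    x <- 10^runif(200, -2, 5)
    y <- eval_logistic(p, x)
    res <- interpolate_concentration(fit, y)
    expect_true(all(res$status == "ok"))
    expect_equal(res$conc, x, tolerance = 1e-9)
  })
})
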