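# synthetic per-run metric rows sharing one analyte/titration/lot scope
metric_rows <- function(ec50s, lot = "Lot-1", run_ids = NULL, dates = NULL) {
  n <- length(ec50s)
  tibble::tibble(
    run_id = run_ids %||% sprintf("run%02d", seq_len(n)),
    acquisition_date = dates %||% sprintf("2012-01-%02d", seq_len(n)),
    analyte = "ENV2", titration = "Standard",
    ec50_4pl = ec50s, ec50_5pl = ec50s * 1.1, auc = ec50s * 10,
    high_mfi = ec50s * 100,
    reagent_lot = lot, isotype = "IgA", conjugate = "PE")
}

test_that("guide-set statistics match closed-form mean and sample SD", {
  gm <- metric_rows(c(10, 12, 14))
  gs <- build_guide_set(gm, gm$run_id)
  st <- gs$stats[gs$stats$metric == "ec50_4pl", ]
  expect_equal(st$mu, 12)
  expect_equal(st$sigma, 2) # sample SD of 10,12,14
  # brute-force oracle
  v <- c(10, 12, 14)
  expect_equal(st$sigma, sqrt(sum((v - mean(v))^2) / 2))

  # single member: mean set, SD absent, warning raised
  expect_warning(gs1 <- build_guide_set(gm[1, ], gm$run_id[1]), "single member")
  st1 <- gs1$stats[gs1$stats$metric == "ec50_4pl", ]
  expect_equal(st1$mu, 10)
  expect_true(is.na(st1$sigma))

  # a member missing one metric: stats over remaining members only
  gm2 <- gm
  gm2$auc[2] <- NA
  gs2 <- build_guide_set(gm2, gm2$run_id)
  expect_equal(gs2$stats$n[gs2$stats$metric == "auc"], 2L)
  expect_equal(gs2$stats$mu[gs2$stats$metric == "auc"], mean(c(100, 140)))

  # mixed lot scope is rejected
  gm3 <- dplyr::bind_rows(gm, metric_rows(11, lot = "Lot-2", run_ids = "runX"))
  expect_error(build_guide_set(gm3, gm3$run_id), class = "xmapqc_usage_error")
})

test_that("expected ranges are nested mu +/- k sigma bands", {
  gm <- metric_rows(c(10, 12, 14))
  gs <- build_guide_set(gm, gm$run_id)
  b <- expected_ranges(gs, "ec50_4pl")
  expect_equal(b$lower, 12 - 1:3 * 2)
  expect_equal(b$upper, 12 + 1:3 * 2)
  expect_true(all(diff(b$upper) > 0) && all(diff(b$lower) < 0))
  # identical members: degenerate bands at the mean
  gs0 <- build_guide_set(metric_rows(c(5, 5, 5)), sprintf("run%02d", 1:3))
  b0 <- expected_ranges(gs0, "ec50_4pl")
  expect_true(all(b0$lower == 5) && all(b0$upper == 5))
  # SD absent propagates to absent bands
  suppressWarnings(gs1 <- build_guide_set(metric_rows(5), "run01"))
  expect_null(expected_ranges(gs1, "ec50_4pl"))
})

test_that("metrics outside mu +/- 3 sigma are flagged; the boundary is inside", {
  gm <- metric_rows(c(10, 12, 14))
  gs <- build_guide_set(gm, gm$run_id)
  mk <- function(v) metric_rows(v, run_ids = "new", dates = "2012-02-01")[1, ]
  # mu=12, sigma=2 -> 3-sigma range [6, 18] for the 4pl EC50
  f_out <- flag_metrics(mk(18.1), gs)
  expect_true("ec50_4pl" %in% f_out$metric)
  expect_true(all(f_out$active))
  f_in <- flag_metrics(mk(17.9), gs)
  expect_false("ec50_4pl" %in% f_in$metric)
  f_bound <- flag_metrics(mk(18), gs)
  expect_false("ec50_4pl" %in% f_bound$metric)
  # member runs are never flagged against their own set
  wild <- metric_rows(1000, run_ids = "run01", dates = "2012-01-01")[1, ]
  expect_equal(nrow(flag_metrics(wild, gs)), 0L)
  # all four metrics participate
  far <- mk(1000)
  expect_setequal(flag_metrics(far, gs)$metric,
                  c("ec50_4pl", "ec50_5pl", "auc", "high_mfi"))
  # no applicable guide set: warning, no flags
  other <- far
  other$reagent_lot <- "Lot-9"
  expect_warning(f_none <- flag_metrics(other, gs), "does not apply")
  expect_equal(nrow(f_none), 0L)
})

test_that("outlier flagging is invariant under affine rescaling of the metric", {
  withr::with_seed(5, {
    base <- metric_rows(rnorm(10, 50, 4))
    gs <- build_guide_set(base, base$run_id)
    probe <- metric_rows(rnorm(20, 50, 8),
                         run_ids = sprintf("p%02d", 1:20),
                         dates = sprintf("2012-03-%02d", 1:20))
    raw_flags <- vapply(seq_len(nrow(probe)), function(i) {
      "ec50_4pl" %in% flag_metrics(probe[i, ], gs)$metric
    }, logical(1))
    # affine transform y = a*x + b applied to guide set and runs alike
    a <- 3.7; b <- -12
    scale_tbl <- function(tb) {
      for (cn in c("ec50_4pl", "ec50_5pl", "auc", "high_mfi")) tb[[cn]] <- a * tb[[cn]] + b
      tb
    }
    gs2 <- build_guide_set(scale_tbl(base), base$run_id)
    scaled_flags <- vapply(seq_len(nrow(probe)), function(i) {
      "ec50_4pl" %in% flag_metrics(scale_tbl(probe[i, ]), gs2)$metric
    }, logical(1))
    expect_identical(raw_flags, scaled_flags)
  })
})

test_that("flag inactivation preserves the record and is idempotent", {
  gm <- metric_rows(c(10, 12, 14))
  gs <- build_guide_set(gm, gm$run_id)
  flags <- flag_metrics(metric_rows(1000, run_ids = "new")[1, ], gs)
  id <- flags$flag_id[flags$metric == "ec50_5pl"]
  f2 <- inactivate_flag(flags, id, comment = "reviewed, acceptable")
  expect_equal(nrow(f2), nrow(flags)) # record retained
  expect_false(f2$active[f2$flag_id == id])
  expect_equal(f2$comment[f2$flag_id == id], "reviewed, acceptable")
  f3 <- inactivate_flag(f2, id, comment = "second look")
  expect_identical(f2, f3) # idempotent: already inactive, unchanged
  expect_error(inactivate_flag(flags, "nope"), class = "xmapqc_usage_error")
})

test_that("Levey-Jennings series orders runs by date and switches band regimes at lots", {
  lot1 <- metric_rows(c(10, 12, 14), lot = "Lot-1",
                      run_ids = sprintf("a%02d", 1:3),
                      dates = sprintf("2012-01-%02d", 1:3))
  lot2 <- metric_rows(c(20, 22, 24), lot = "Lot-2",
                      run_ids = sprintf("b%02d", 1:3),
                      dates = sprintf("2012-02-%02d", 1:3))
  later1 <- metric_rows(13, lot = "Lot-1", run_ids = "a99", dates = "2012-01-20")
  later2 <- metric_rows(40, lot = "Lot-2", run_ids = "b99", dates = "2012-02-20")
  all_runs <- dplyr::bind_rows(lot1, lot2, later1, later2)
  gss <- list(build_guide_set(lot1, lot1$run_id),
              build_guide_set(lot2, lot2$run_id))
  s <- levey_jennings_series(all_runs, gss, "ec50_4pl")
  expect_equal(nrow(s), 8L)
  expect_equal(s$run_id, c("a01", "a02", "a03", "a99", "b01", "b02", "b03", "b99"))
  # two band regimes
  expect_equal(unique(s$mu[s$reagent_lot == "Lot-1"]), 12)
  expect_equal(unique(s$mu[s$reagent_lot == "Lot-2"]), 22)
  # only the wild Lot-2 run is flagged (40 > 22 + 3*2)
  expect_equal(s$run_id[s$flagged], "b99")

  # a run lacking any guide set is emitted unbanded
  orphan <- metric_rows(15, lot = "Lot-3", run_ids = "c01", dates = "2012-03-01")
  s2 <- levey_jennings_series(orphan, gss, "ec50_4pl")
  expect_true(is.na(s2$mu))
  expect_false(s2$flagged)
})
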