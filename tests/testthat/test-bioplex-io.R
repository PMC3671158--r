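test_that("sample type codes map to roles with optional index, case-insensitively", {
  expect_equal(parse_sample_type("S3"), list(sample_role = "standard", sample_index = 3L))
  expect_equal(parse_sample_type("B"), list(sample_role = "background", sample_index = NA_integer_))
  expect_equal(parse_sample_type("x12"), list(sample_role = "unknown", sample_index = 12L))
  expect_equal(parse_sample_type("c2")$sample_role, "qc_control")
  expect_error(parse_sample_type("Q7"), class = "xmapqc_format_error", regexp = "Q7")
  expect_error(parse_sample_type(""), class = "xmapqc_format_error")
})

test_that("table kind is detected from the well-location column", {
  expect_equal(detect_table_kind(c("Type", "Well", "Description", "FI")), "raw")
  expect_equal(detect_table_kind(c("Type", "Wells", "Description", "FI")), "summary")
  expect_error(detect_table_kind(c("Type", "Description", "FI")),
               class = "xmapqc_format_error")
})

test_that("a generated workbook parses back to the ground-truth well table", {
  qr <- quick_run(seed = 5)
  run <- qr$run
  truth <- qr$truth$wells

  expect_equal(run$analytes, c("ENV1", "ENV2"))
  expect_equal(unname(run$bead_numbers), c(34L, 35L))
  expect_equal(nrow(run$wells), nrow(truth))

  # align on (analyte, well) and compare roles, dilutions and FI
  key_r <- paste(run$wells$analyte, run$wells$well)
  key_t <- paste(truth$analyte, truth$well)
  idx <- match(key_t, key_r)
  expect_false(anyNA(idx))
  expect_equal(run$wells$fi[idx], truth$fi, tolerance = 1e-12)
  expect_equal(run$wells$dilution[idx], truth$dilution)
  expect_equal(run$wells$sample_id[idx], truth$sample_id)
  expect_equal(run$wells$description[idx], truth$description)
  # standards carry the expected concentration; unknowns do not
  std <- run$wells$sample_role[idx] == "standard"
  expect_equal(run$wells$expected_conc[idx][std],
               truth$expected_conc[std], tolerance = 1e-12)
  expect_true(all(is.na(run$wells$expected_conc[idx][run$wells$sample_role[idx] == "unknown"])))
  # header metadata captured
  expect_equal(run$metadata$run_name, "synthetic run")
  expect_equal(run$metadata$reagent_lot, "Lot-1")
  expect_equal(run$metadata$isotype, "IgA")
})

test_that("parsing is pure and footers are captured opaquely", {
  path <- tempfile(fileext = ".xlsx")
  generate_run_workbook(quick_config(seed = 2), path)
  r1 <- parse_workbook(path)
  r2 <- parse_workbook(path)
  expect_identical(r1$wells, r2$wells)
  expect_identical(r1$metadata, r2$metadata)
  expect_true(length(r1$footers) > 0)
  expect_match(r1$footers[["ENV1"]][1], "complete")
  unlink(path)
})

test_that("workbooks with both summary and raw tables capture both row kinds", {
  path <- tempfile(fileext = ".xlsx")
  generate_run_workbook(quick_config(seed = 3, include_summary = TRUE), path)
  run <- parse_workbook(path)
  kinds <- table(run$wells$row_kind)
  expect_true(kinds[["raw"]] > 0 && kinds[["summary"]] > 0)
  # summary rows list all replicate wells, comma-separated; raw rows one well
  summ <- run$wells[run$wells$row_kind == "summary" & run$wells$sample_id == "S1" &
                      run$wells$analyte == "ENV1", ]
  expect_equal(nrow(summ), 1L)
  expect_length(strsplit(summ$well, ",")[[1]], 2L)
  expect_true(all(is.na(run$wells$bead_count[run$wells$row_kind == "summary"])))
  expect_true(all(!is.na(run$wells$bead_count[run$wells$row_kind == "raw"])))
  # summary rows carry the file's reported %CV
  expect_true(all(is.finite(summ$reported_pct_cv)))
  unlink(path)
})

test_that("degenerate workbooks produce format errors naming the sheet", {
  # sheet with no Type header row
  path <- tempfile(fileext = ".xlsx")
  xmapqc:::write_xlsx_minimal(list("ENV9" = list(list("Just", "metadata"))), path)
  expect_error(parse_workbook(path), class = "xmapqc_format_error", regexp = "ENV9")
  unlink(path)

  # duplicate well position within one raw table
  path2 <- tempfile(fileext = ".xlsx")
  xmapqc:::write_xlsx_minimal(list("ENV1" = list(
    list("Type", "Well", "FI"),
    list("S1", "A1", 100), list("S1", "A1", 120))), path2)
  expect_error(parse_workbook(path2), class = "xmapqc_format_error",
               regexp = "duplicate well")
  unlink(path2)

  # unparseable numeric: fail-fast by default, skip with warning when lenient
  path3 <- tempfile(fileext = ".xlsx")
  xmapqc:::write_xlsx_minimal(list("ENV1" = list(
    list("Type", "Well", "FI"),
    list("S1", "A1", "oops"), list("S2", "A2", 120))), path3)
  expect_error(parse_workbook(path3), class = "xmapqc_format_error",
               regexp = "oops")
  expect_warning(run <- parse_workbook(path3, lenient = TRUE), "oops")
  expect_equal(nrow(run$wells), 2L) # row kept, cell NA
  unlink(path3)
})

test_that("multi-file merge lets one file's standards serve another's unknowns", {
  # fragment A: standards only; fragment B: unknowns only, same analyte
  cfgA <- synth_config(
    analytes = list(list(name = "ENV1", bead_number = 34,
                         params = logistic_params(50, 30000, m = 120, h = 1))),
    standard_dilutions = 3^(0:7), n_replicates = 2L, unknowns = list(),
    noise_cv = 0, seed = 1)
  cfgB <- synth_config(
    analytes = list(list(name = "ENV1", bead_number = 34,
                         params = logistic_params(50, 30000, m = 120, h = 1))),
    standard_dilutions = 3^(0:7), n_replicates = 2L,
    unknowns = list(list(id = "U1", conc = 500, dilution = 100)),
    noise_cv = 0, seed = 2)
  pa <- tempfile(fileext = ".xlsx"); pb <- tempfile(fileext = ".xlsx")
  generate_run_workbook(cfgA, pa)
  generate_run_workbook(cfgB, pb)
  fa <- parse_workbook(pa)
  fb <- parse_workbook(pb)
  # strip standards from B to emulate a results-only file
  fb$wells <- fb$wells[fb$wells$sample_role != "standard", ]
  merged <- merge_run_files(list(fa, fb))
  expect_setequal(unique(merged$wells$source_file), c(basename(pa), basename(pb)))
  an <- analyze_run(merged, xmap_options(models = "fourpl", interp_model = "fourpl"))
  got <- an$interp[an$interp$sample_id == "X1", ]
  expect_equal(got$conc, 500, tolerance = 1e-3) # noiseless: near-exact recovery
  unlink(c(pa, pb))

  # single fragment: identity
  expect_identical(merge_run_files(list(fa)), fa)

  # conflicting bead numbers for the same analyte name
  fc <- fa
  fc$bead_numbers[["ENV1"]] <- 35L
  expect_error(merge_run_files(list(fa, fc)), class = "xmapqc_merge_error")
})

test_that("canonical outputs are complete, stable and conserve rows", {
  qr <- quick_run(seed = 9)
  an <- analyze_run(qr$run)
  d1 <- file.path(tempdir(), "canon1"); d2 <- file.path(tempdir(), "canon2")
  p1 <- write_canonical(an, d1)
  expect_length(p1, 3L)
  write_canonical(an, d2)
  for (f in c("wells.csv", "curves.csv", "metrics.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  wells_csv <- utils::read.csv(file.path(d1, "wells.csv"))
  expect_equal(nrow(wells_csv), nrow(qr$run$wells))
  metrics_csv <- utils::read.csv(file.path(d1, "metrics.csv"))
  expect_equal(nrow(metrics_csv), 2L) # one per analyte x titration

  # excluding a whole analyte keeps its metric row, with empty cells
  res <- apply_exclusion(an, exclusion("analyte", "ENV2", reason = "test"))
  d3 <- file.path(tempdir(), "canon3")
  write_canonical(res$analysis, d3)
  m3 <- utils::read.csv(file.path(d3, "metrics.csv"))
  expect_equal(nrow(m3), 2L)
  expect_true(all(is.na(m3[m3$analyte == "ENV2",
                           c("ec50_4pl", "ec50_5pl", "auc", "high_mfi")])))
  w3 <- utils::read.csv(file.path(d3, "wells.csv"))
  expect_equal(nrow(w3), nrow(wells_csv)) # rows conserved, only status changed
  unlink(c(d1, d2, d3), recursive = TRUE)
})
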