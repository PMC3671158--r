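# Small, fast synthetic configurations shared across tests.

quick_config <- function(seed = 1L, ...) {
  synth_config(
    analytes = list(
      list(name = "ENV1", bead_number = 34,
           params = logistic_params(50, 30000, m = 120, h = 1)),
      list(name = "ENV2", bead_number = 35,
           params = logistic_params(40, 25000, m = 80, h = 1.2))
    ),
    standard_dilutions = 3^(0:7), n_replicates = 2L,
    unknowns = list(list(id = "U1", conc = 500, dilution = 100)),
    seed = seed, ...
  )
}

quick_run <- function(seed = 1L, ...) {
  path <- tempfile(fileext = ".xlsx")
  res <- generate_run_workbook(quick_config(seed = seed, ...), path)
  run <- parse_workbook(path)
  unlink(c(path, res$truth_path))
  list(run = run, truth = res$truth)
}

# single standard titration of noiseless/noisy points from known truth
make_points <- function(params, doses = 10000 / 3^(0:9), noise_cv = 0,
                        seed = NULL) {
  f <- function() {
    y <- vapply(doses, function(d) simulate_well_fi(params, d, noise_cv), double(1))
    tibble::tibble(dose = doses, mean_response = y, excluded = FALSE)
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
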