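# Reading instrument run workbooks into the canonical data model.
#
# Each workbook carries one worksheet per bead type (analyte). A sheet is
# laid out as: header metadata rows (key/value pairs), one or two data
# tables (raw per-well and/or summary per-sample), and an opaque footer.
# The metadata/table boundary is the first row whose first cell is "Type";
# a table ends at the first fully blank row.

SAMPLE_ROLES <- c("background", "standard", "qc_control", "control", "unknown")

# canonical column dialect (matched case-insensitively, punctuation-tolerant)
CANON_COLS <- c(
  "type" = "sample_id", "well" = "well", "wells" = "well",
  "description" = "description", "fi" = "fi", "fi - bkgd" = "fi_bkgd",
  "fi-bkgd" = "fi_bkgd", "%cv" = "reported_pct_cv", "cv" = "reported_pct_cv",
  "std dev" = "std_dev", "obs conc" = "obs_conc", "exp conc" = "expected_conc",
  "dilution" = "dilution", "bead count" = "bead_count"
)

NUMERIC_WELL_COLS <- c("fi", "fi_bkgd", "reported_pct_cv", "std_dev",
                       "obs_conc", "expected_conc", "dilution", "bead_count")

# header metadata keys promoted to named RunMetadata fields
META_KEYS <- c(
  "file name" = "run_name", "run name" = "run_name",
  "acquisition date" = "acquisition_date", "acq. date" = "acquisition_date",
  "isotype" = "isotype", "conjugate" = "conjugate",
  "performer" = "performer", "operator" = "performer",
  "reagent lot" = "reagent_lot", "std lot" = "reagent_lot",
  "batch" = "batch_id", "batch id" = "batch_id"
)

empty_metadata <- function() {
  list(run_name = NA_character_, acquisition_date = NA_character_,
       isotype = NA_character_, conjugate = NA_character_,
       performer = NA_character_, reagent_lot = NA_character_,
       batch_id = NA_character_, extra = list())
}

#' Parse a sample type code
#'
#' Leading letters give the sample role (`B` background, `S` standard,
#' `C` quality control, `X` unknown; case-insensitive); trailing digits, if
#' any, give the sample index.
#'
#' @param code Sample type code as printed in the workbook, e.g. `"S3"`.
#' @return List with `sample_role` and `sample_index` (`NA` when absent).
#' @export
#' @examples
#' parse_sample_type("S3")  # standard, index 3
#' parse_sample_type("x12") # unknown, index 12
parse_sample_type <- function(code) {
  if (is.na(code) || !nzchar(trimws(code))) stop_format("empty sample type code")
  code <- trimws(code)
  m <- regmatches(code, regexec("^([A-Za-z]+)\\s*([0-9]*)$", code))[[1]]
  if (length(m) == 0L) stop_format(sprintf("unrecognized sample type code: '%s'", code))
  role <- switch(toupper(m[2]),
                 "B" = "background", "S" = "standard",
                 "C" = "qc_control", "X" = "unknown", NULL)
  if (is.null(role)) stop_format(sprintf("unrecognized sample type code: '%s'", code))
  idx <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
  list(sample_role = role, sample_index = idx)
}

#' Classify a data-table header row as raw or summary
#'
#' Raw (per-well) tables carry a singular `Well` column; summary
#' (per-sample) tables carry `Wells`.
#'
#' @param header_cells Character vector of header-cell labels.
#' @return `"raw"` or `"summary"`.
#' @export
detect_table_kind <- function(header_cells) {
  norm <- tolower(trimws(as.character(header_cells)))
  if ("well" %in% norm) return("raw")
  if ("wells" %in% norm) return("summary")
  stop_format("data-table header has neither a 'Well' nor a 'Wells' column")
}

parse_sheet_name <- function(sheet) {
  m <- regmatches(sheet, regexec("^(.*?)\\s*\\(([0-9]+)\\)\\s*$", sheet))[[1]]
  if (length(m) == 3L) list(analyte = m[2], bead_number = as.integer(m[3]))
  else list(analyte = trimws(sheet), bead_number = NA_integer_)
}

empty_wells <- function() {
  tibble::tibble(
    analyte = character(), bead_number = integer(), sample_role = character(),
    sample_index = integer(), sample_id = character(), description = character(),
    well = character(), row_kind = character(), dilution = double(),
    expected_conc = double(), fi = double(), fi_bkgd = double(),
    reported_pct_cv = double(), std_dev = double(), obs_conc = double(),
    bead_count = double(), extra_cols = character(), source_file = character()
  )
}

new_run <- function(metadata = empty_metadata(), analytes = character(),
                    bead_numbers = integer(), wells = empty_wells(),
                    footers = list(), source_files = character()) {
  structure(list(metadata = metadata, analytes = analytes,
                 bead_numbers = bead_numbers, wells = wells,
                 footers = footers, source_files = source_files),
            class = "xmap_run")
}

#' @export
print.xmap_run <- function(x, ...) {
  cat(sprintf("<xmap_run> '%s': %d analyte(s), %d well record(s), %d source file(s)\n",
              x$metadata$run_name %||% "?", length(x$analytes), nrow(x$wells),
              length(x$source_files)))
  invisible(x)
}

parse_num_cell <- function(val, sheet, row, col, lenient) {
  if (is.na(val) || !nzchar(trimws(val))) return(NA_real_)
  out <- suppressWarnings(as.numeric(val))
  if (is.na(out)) {
    msg <- sprintf("unparseable numeric cell '%s' (sheet '%s', row %d, column '%s')",
                   val, sheet, row, col)
    if (lenient) {
      warn(msg)
      return(NA_real_)
    }
    stop_format(msg)
  }
  out
}

parse_one_table <- function(grid, hdr_row, end_row, sheet, info, source_file, lenient) {
  header <- trimws(as.character(grid[hdr_row, ]))
  kind <- detect_table_kind(header)
  norm_hdr <- tolower(header)
  mapped <- unname(CANON_COLS[norm_hdr])
  rows <- list()
  seen_wells <- character(0)
  for (r in seq(hdr_row + 1L, length.out = max(0L, end_row - hdr_row))) {
    cells <- as.character(grid[r, ])
    if (all(is.na(cells) | !nzchar(trimws(cells)))) break
    rec <- as.list(empty_wells()[0, ])
    vals <- list(extra = character(0))
    for (j in seq_along(header)) {
      cn <- mapped[j]
      v <- cells[j]
      if (is.na(norm_hdr[j]) || !nzchar(norm_hdr[j])) next
      if (is.na(cn)) {
        if (!is.na(v) && nzchar(trimws(v))) {
          vals$extra <- c(vals$extra, sprintf("%s=%s", header[j], trimws(v)))
        }
      } else if (cn %in% NUMERIC_WELL_COLS) {
        vals[[cn]] <- parse_num_cell(v, sheet, r, header[j], lenient)
      } else {
        vals[[cn]] <- if (is.na(v)) NA_character_ else trimws(v)
      }
    }
    if (is.null(vals$sample_id) || is.na(vals$sample_id)) {
      next # blank Type cell: not a data row
    }
    st <- parse_sample_type(vals$sample_id)
    well <- vals$well %||% NA_character_
    if (kind == "raw") {
      if (!is.na(well)) {
        if (well %in% seen_wells) {
          stop_format(sprintf("duplicate well '%s' in raw table of sheet '%s'", well, sheet))
        }
        seen_wells <- c(seen_wells, well)
      }
    } else if (!is.na(well)) {
      # summary rows list multiple wells; normalize comma+whitespace
      well <- paste(trimws(strsplit(well, ",")[[1]]), collapse = ",")
    }
    dil <- vals$dilution %||% NA_real_
    if (is.na(dil)) dil <- 1
    if (dil <= 0) stop_format(sprintf("non-positive dilution in sheet '%s', row %d", sheet, r))
    exp_conc <- vals$expected_conc %||% NA_real_
    if (!st$sample_role %in% c("standard", "qc_control")) exp_conc <- NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analyte = info$analyte, bead_number = info$bead_number,
      sample_role = st$sample_role, sample_index = st$sample_index,
      sample_id = vals$sample_id,
      description = vals$description %||% NA_character_,
      well = well, row_kind = kind, dilution = dil,
      expected_conc = exp_conc, fi = vals$fi %||% NA_real_,
      fi_bkgd = vals$fi_bkgd %||% NA_real_,
      reported_pct_cv = vals$reported_pct_cv %||% NA_real_,
      std_dev = vals$std_dev %||% NA_real_,
      obs_conc = vals$obs_conc %||% NA_real_,
      bead_count = if (kind == "raw") vals$bead_count %||% NA_real_ else NA_real_,
      extra_cols = if (length(vals$extra)) paste(vals$extra, collapse = ";") else NA_character_,
      source_file = source_file
    )
  }
  dplyr::bind_rows(empty_wells(), rows)
}

#' Read one instrument run workbook
#'
#' Parses every worksheet of a Bio-Plex-Manager-style workbook into a run
#' fragment: one analyte per sheet, header key/value metadata, raw and/or
#' summary data tables, and opaque footer annotations. The input file is
#' never modified.
#'
#' @param path Path to an `.xlsx`/`.xls` workbook.
#' @param lenient If `TRUE`, rows with unparseable numeric cells are skipped
#'   with a warning instead of failing the parse.
#' @return An `xmap_run` fragment.
#' @export
parse_workbook <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("workbook not found: %s", path))
  sheets <- readxl::excel_sheets(path)
  if (length(sheets) == 0L) stop_format(sprintf("workbook '%s' has no worksheets", path))

  metadata <- empty_metadata()
  analytes <- character(0)
  bead_numbers <- integer(0)
  footers <- list()
  all_wells <- list()

  for (sheet in sheets) {
    suppressMessages(
      grid <- readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                                 col_types = "text", .name_repair = "minimal")
    )
    grid <- as.data.frame(grid, stringsAsFactors = FALSE)
    if (nrow(grid) == 0L) {
      stop_format(sprintf("sheet '%s' has no data-table header row ('Type')", sheet))
    }
    first_cell <- trimws(as.character(grid[[1]]))
    hdr_rows <- which(!is.na(first_cell) & tolower(first_cell) == "type")
    if (length(hdr_rows) == 0L) {
      stop_format(sprintf("sheet '%s' has no data-table header row ('Type')", sheet))
    }
    info <- parse_sheet_name(sheet)
    analytes <- c(analytes, info$analyte)
    bead_numbers <- c(bead_numbers, setNames(info$bead_number, info$analyte))

    # header metadata: rows above the first table header
    for (r in seq_len(hdr_rows[1] - 1L)) {
      key <- first_cell[r]
      if (is.na(key) || !nzchar(key)) next
      val <- if (ncol(grid) >= 2L) trimws(as.character(grid[r, 2L])) else NA_character_
      key_norm <- tolower(sub(":$", "", key))
      if (key_norm %in% names(META_KEYS)) {
        field <- META_KEYS[[key_norm]]
        if (is.na(metadata[[field]])) metadata[[field]] <- val
      } else if (is.null(metadata$extra[[key]])) {
        metadata$extra[[key]] <- val
      }
    }

    # tables: each header row starts a table ending at the first blank row
    table_rows <- integer(0)
    for (h in hdr_rows) {
      end <- nrow(grid)
      for (r in seq(h + 1L, length.out = max(0L, nrow(grid) - h))) {
        cells <- as.character(grid[r, ])
        if (all(is.na(cells) | !nzchar(trimws(cells)))) {
          end <- r - 1L
          break
        }
      }
      all_wells[[length(all_wells) + 1L]] <-
        parse_one_table(grid, h, end, sheet, info, basename(path), lenient)
      table_rows <- c(table_rows, h:end)
    }

    # footer: non-blank rows after the first table that are not in any table
    tail_rows <- setdiff(seq(hdr_rows[1], nrow(grid)), table_rows)
    foot <- character(0)
    for (r in tail_rows) {
      cells <- as.character(grid[r, ])
      cells <- cells[!is.na(cells) & nzchar(trimws(cells))]
      if (length(cells)) foot <- c(foot, paste(trimws(cells), collapse = " | "))
    }
    if (length(foot)) footers[[info$analyte]] <- foot
  }

  if (is.na(metadata$run_name)) {
    metadata$run_name <- sub("\\.(xlsx|xls)$", "", basename(path))
  }
  wells <- dplyr::bind_rows(empty_wells(), all_wells)
  new_run(metadata = metadata, analytes = unique(analytes),
          bead_numbers = bead_numbers[unique(analytes)], wells = wells,
          footers = footers, source_files = basename(path))
}

#' Merge run fragments from several workbook files into one run
#'
#' Several files can be imported as one run, so that standard titrations in
#' one file serve analytes whose results sit in another. Wells are
#' concatenated in file order with their source file retained; an identical
#' analyte name must carry the same bead number everywhere it appears.
#'
#' @param fragments List of `xmap_run` fragments from [parse_workbook()].
#' @return A single merged `xmap_run`.
#' @export
merge_run_files <- function(fragments) {
  if (length(fragments) == 0L) stop_usage("at least one run fragment is required")
  if (!all(vapply(fragments, inherits, logical(1), "xmap_run"))) {
    stop_usage("all fragments must be `xmap_run` objects")
  }
  if (length(fragments) == 1L) return(fragments[[1]])

  metadata <- empty_metadata()
  bead_numbers <- integer(0)
  analytes <- character(0)
  footers <- list()
  for (fr in fragments) {
    for (f in setdiff(names(metadata), "extra")) {
      if (is.na(metadata[[f]]) && !is.na(fr$metadata[[f]])) metadata[[f]] <- fr$metadata[[f]]
    }
    metadata$extra <- modifyList(fr$metadata$extra, metadata$extra)
    for (a in fr$analytes) {
      bn <- fr$bead_numbers[[a]]
      if (a %in% names(bead_numbers)) {
        old <- bead_numbers[[a]]
        if (!is.na(old) && !is.na(bn) && old != bn) {
          stop_merge(sprintf("conflicting bead numbers for analyte '%s': %d vs %d", a, old, bn))
        }
        if (is.na(old)) bead_numbers[[a]] <- bn
      } else {
        bead_numbers[[a]] <- bn
        analytes <- c(analytes, a)
      }
    }
    for (a in names(fr$footers)) footers[[a]] <- c(footers[[a]], fr$footers[[a]])
  }
  wells <- dplyr::bind_rows(lapply(fragments, function(fr) fr$wells))
  new_run(metadata = metadata, analytes = analytes,
          bead_numbers = bead_numbers[analytes], wells = wells,
          footers = footers,
          source_files = unique(unlist(lapply(fragments, function(fr) fr$source_files))))
}
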