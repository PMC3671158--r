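# Minimal SpreadsheetML (.xlsx) writer used by the synthetic-data module.
# Strings are written as inline strings and numbers as plain values, which
# is all the instrument-workbook dialect needs. Entry timestamps are pinned
# so the same content always produces byte-identical archives.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_col_letter <- function(j) {
  s <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    s <- paste0(LETTERS[r + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

# cells: list of rows, each row a list of scalars (NA/NULL = blank cell).
xlsx_sheet_xml <- function(cells) {
  rows <- character(0)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    cs <- character(0)
    for (j in seq_along(row)) {
      v <- row[[j]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) next
      ref <- paste0(xlsx_col_letter(j), i)
      if (is.numeric(v)) {
        cs <- c(cs, sprintf('<c r="%s"><v>%s</v></c>', ref, sprintf("%.15g", v)))
      } else {
        cs <- c(cs, sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                            ref, xml_escape(as.character(v))))
      }
    }
    if (length(cs) > 0L) {
      rows <- c(rows, sprintf('<row r="%d">%s</row>', i, paste0(cs, collapse = "")))
    }
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')
}

# sheets: named list (sheet name -> cells as above).
write_xlsx_minimal <- function(sheets, path) {
  stopifnot(length(sheets) >= 1L, !is.null(names(sheets)))
  tmp <- tempfile("xlsx")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  n <- length(sheets)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste0(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                   seq_len(n)), collapse = ""),
    '</Types>'), file.path(tmp, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste0(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                   xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    '</sheets></workbook>'), file.path(tmp, "xl", "workbook.xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                   seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  for (i in seq_len(n)) {
    writeLines(xlsx_sheet_xml(sheets[[i]]),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }

  files <- list.files(tmp, recursive = TRUE, all.files = TRUE, full.names = TRUE)
  Sys.setFileTime(files, as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  zip::zip(zipfile = path,
           files = list.files(tmp, recursive = TRUE, all.files = TRUE),
           root = tmp, mode = "mirror", include_directories = FALSE)
  invisible(path)
}
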