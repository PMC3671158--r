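# Internal helpers shared across modules.

# Classed error constructors so callers (and the CLI) can distinguish
# usage errors from data/format errors.
stop_format <- function(msg, ...) abort(msg, class = "xmapqc_format_error", ...)
stop_merge <- function(msg, ...) abort(msg, class = "xmapqc_merge_error", ...)
stop_fit <- function(msg, ...) abort(msg, class = "xmapqc_fit_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "xmapqc_config_error", ...)
stop_io <- function(msg, ...) abort(msg, class = "xmapqc_io_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "xmapqc_domain_error", ...)
stop_usage <- function(msg, ...) abort(msg, class = "xmapqc_usage_error", ...)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Format a double so that writing and re-reading round-trips to full
# double precision (used by both the workbook writer and canonical CSVs).
num_chr <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.15g", x[ok])
  out
}

# "A1"-style well label helpers. Row letters extend past 'H' so plates
# larger than 96 wells are representable.
well_label <- function(i, n_cols = 12L) {
  row <- (i - 1L) %/% n_cols + 1L
  col <- (i - 1L) %% n_cols + 1L
  paste0(LETTERS[row], col)
}

is_well_label <- function(x) grepl("^[A-Za-z]+[0-9]+$", x)
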