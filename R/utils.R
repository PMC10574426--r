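# Internal helpers shared across modules.

# Fail with a consistent message when required columns are absent.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (!is.numeric(x) || any(!is.finite(x) & !(allow_na & is.na(x)))) {
    abort(sprintf("`%s` must be finite and numeric", name))
  }
  bad <- !is.na(x) & (x < min | x > max)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in [%s, %s]", name, format(min), format(max)))
  }
  invisible(x)
}

# Gene symbols are compared case-insensitively after trimming; sources mix
# capitalization conventions and no alias resolution is attempted.
normalize_gene <- function(x) toupper(trimws(x))

normalize_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
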