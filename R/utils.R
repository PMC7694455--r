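# Internal helpers shared across modules.

# Classed error so callers (and tests) can branch on failure kind rather than
# matching message text.
pk_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("phenokit_", class), "phenokit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

pk_warn <- function(message, class) {
  warning(structure(
    class = c(paste0("phenokit_", class), "phenokit_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# Check that `df` has the named columns; error names the file/stream for
# actionable messages from the pipeline.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    pk_stop(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "schema"
    )
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
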