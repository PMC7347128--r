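# Internal helpers shared across modules.

# Deterministic sub-seed for a named random stream, derived from the global
# seed so partial pipelines are independently reproducible. Kept < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((as.numeric(seed) * 2654435L + offset) %% .Machine$integer.max)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "blight311_config_error", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "blight311_data_error", ...)
}

stop_numeric <- function(msg, ...) {
  abort(msg, class = "blight311_numeric_error", ...)
}

assert_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_config(sprintf(
      "%s: missing required column(s): %s",
      where, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
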