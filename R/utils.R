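# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("nitroflood_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'", name, "' must be a single finite number")
  if (x < lower || (strict_lower && x <= lower))
    stop_input("'", name, "' must be ", if (strict_lower) "> " else ">= ", lower)
  if (x > upper || (strict_upper && x >= upper))
    stop_input("'", name, "' must be ", if (strict_upper) "< " else "<= ", upper)
  invisible(x)
}

# Deterministic 32-bit sub-seed derived from a master seed and a stream name,
# so regenerating one table never perturbs the draws of another.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Format a data.frame for CSV output at 6 significant digits.
format_sig <- function(df, digits = 6) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  df
}

write_csv_sig <- function(df, path, digits = 6) {
  utils::write.csv(format_sig(df, digits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_input(what, ": missing column(s) ", paste(miss, collapse = ", "))
  invisible(df)
}
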