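#' Centered moving average with shrinking edge windows
#'
#' Smooths a numeric series with a centered moving average. Near the ends the
#' window shrinks symmetrically so that the output has the same length as the
#' input and no data are fabricated: at index `i` the half-width is the largest
#' value that keeps the window inside the series, down to a single point at the
#' first and last index.
#'
#' @param x Numeric vector.
#' @param window Odd integer window size (default 5, the standard smoothing
#'   span used for bleaching-coefficient series).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5))           # edges untouched, center = 3
#' moving_average(rep(2, 10))                 # constants are preserved
#' @export
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L) {
    abort("`window` must be a positive integer.")
  }
  if (window %% 2L == 0L) {
    abort("`window` must be odd so the moving average is centered.")
  }
  n <- length(x)
  if (n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

# shared column contract for long-format trace tables
trace_cols <- c("roi_id", "channel", "frame", "time_s", "value")

assert_trace_table <- function(traces, what = "traces") {
  missing <- setdiff(trace_cols, names(traces))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(traces)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf("`%s` = %s is outside its valid range.", name, format(x)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer that preserves doubles bit-exactly (%.17g round-trips IEEE 754)
write_csv_full <- function(df, path) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
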