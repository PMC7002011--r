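#' Half-time of a first-order recruitment process
#'
#' Time at which `a (1 - e^(-b t))` reaches half its plateau: `ln(2) / b`.
#'
#' @param b Rate constant per second (> 0).
#' @return Half-time in seconds.
#' @examples
#' half_time(log(2))   # 1 s
#' @export
half_time <- function(b) {
  if (any(!is.finite(b)) || any(b <= 0)) abort("`b` must be positive and finite.")
  log(2) / b
}

#' Fit a saturating exponential to a net recruitment trace
#'
#' Least-squares fit of `y = a (1 - e^(-b t))` by bounded Levenberg-Marquardt
#' (via \pkg{minpack.lm}), with `a, b > 0`. Initialization: `a0` is the mean
#' of the final five points (plateau proxy); `b0 = ln(2) / t*` where `t*` is
#' the first time the trace exceeds `a0 / 2` (mid-series time as fallback).
#' With `normalize = TRUE` the values are first divided by the plateau proxy,
#' so the fitted `a` is close to 1; `b` and the half-time are invariant to
#' this rescaling.
#'
#' @param times Times in seconds, starting at 0, strictly increasing.
#' @param values Net trace values (zero at t0).
#' @param normalize Divide by the mean of the final 5 points before fitting.
#' @param window_s Optional: restrict the fit to `times <= window_s`.
#' @return A `recruitment_fit` object: plateau `a`, rate `b`, `t_half`
#'   (`ln(2)/b`), residual sum of squares `rss`, `converged`, `n_points`,
#'   `window_s`, and the data with fitted values. Non-convergent fits return
#'   `converged = FALSE` with `NA` parameters rather than erroring.
#' @export
fit_saturating_exponential <- function(times, values, normalize = FALSE,
                                       window_s = NULL) {
  if (length(times) != length(values)) abort("`times` and `values` lengths differ.")
  if (!is.null(window_s)) {
    keep <- times <= window_s + 1e-9
    times <- times[keep]; values <- values[keep]
  }
  if (length(times) < 4L) abort("Need at least 4 points to fit the model.")
  if (abs(times[1]) > 1e-9) abort("`times` must start at 0 (net traces are zero-referenced).")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")

  failed <- function() {
    structure(list(a = NA_real_, b = NA_real_, t_half = NA_real_,
                   rss = NA_real_, converged = FALSE,
                   n_points = length(times),
                   window_s = window_s %||% max(times),
                   normalized = normalize,
                   data = tibble(time_s = times, value = values,
                                 fitted = NA_real_)),
              class = "recruitment_fit")
  }

  plateau_proxy <- mean(tail(values, 5L))
  if (!is.finite(plateau_proxy) || plateau_proxy <= 0) return(failed())
  y <- if (normalize) values / plateau_proxy else values
  a0 <- mean(tail(y, 5L))
  above <- which(y > a0 / 2 & times > 0)
  t_star <- if (length(above) > 0) times[above[1]] else times[ceiling(length(times) / 2)]
  b0 <- log(2) / t_star

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * (1 - exp(-b * t)),
      data = list(y = y, t = times),
      start = list(a = a0, b = b0),
      lower = c(a = 1e-12, b = 1e-12),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  est <- coef(fit)
  if (!all(is.finite(est)) || est[["b"]] <= 1e-10) return(failed())

  fitted_y <- est[["a"]] * (1 - exp(-est[["b"]] * times))
  structure(list(
    a = unname(est[["a"]]), b = unname(est[["b"]]),
    t_half = log(2) / unname(est[["b"]]),
    rss = sum((y - fitted_y)^2),
    converged = TRUE,
    n_points = length(times),
    window_s = window_s %||% max(times),
    normalized = normalize,
    data = tibble(time_s = times, value = y, fitted = fitted_y)
  ), class = "recruitment_fit")
}

#' @export
print.recruitment_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<recruitment_fit: did not converge>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<recruitment_fit> a = %.4g, b = %.4g /s, t_half = %.4g s (rss %.3g, %d points over %.3g s)\n",
    x$a, x$b, x$t_half, x$rss, x$n_points, x$window_s))
  invisible(x)
}

#' @export
tidy.recruitment_fit <- function(x, ...) {
  tibble(term = c("a", "b", "t_half"),
         estimate = c(x$a, x$b, x$t_half))
}

#' @export
glance.recruitment_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, t_half = x$t_half, rss = x$rss,
         converged = x$converged, n_points = x$n_points, window_s = x$window_s)
}

#' @export
autoplot.recruitment_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#d95f02",
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "net signal (a.u.)",
                  title = if (object$converged) {
                    sprintf("a(1 - e^{-bt}) fit: t½ = %.2f s", object$t_half)
                  } else "saturating-exponential fit (not converged)") +
    ggplot2::theme_minimal()
}

#' Per-cell recruitment half-times from net traces
#'
#' Fits each cell's net trace individually (after normalization to its own
#' plateau proxy) and returns one row per ROI. This is the single-cell RFP
#' protocol; failed fits are kept in the table with `converged = FALSE` and
#' excluded from summaries.
#'
#' @param traces Net trace tibble (one channel).
#' @param window_s Optional fit window in seconds.
#' @return Tibble with `roi_id`, `a`, `b`, `t_half`, `rss`, `converged`,
#'   `n_points`; summarize with [fit_summary()].
#' @export
single_cell_half_times <- function(traces, window_s = NULL) {
  assert_trace_table(traces)
  if (nrow(traces) == 0) abort("No traces to fit.")
  if (n_distinct(traces$channel) > 1L) {
    abort("Traces span several channels; filter to one channel before fitting.")
  }
  traces %>%
    group_by(.data$roi_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      f <- fit_saturating_exponential(d$time_s, d$value, normalize = TRUE,
                                      window_s = window_s)
      glance(f) %>% select(-"window_s")
    }) %>%
    ungroup()
}

#' Summaries of a table of single-cell fits
#'
#' Median and quartiles of the converged half-times, plus counts of failed
#' fits (the summary statistics behind half-time box plots).
#'
#' @param fits Output of [single_cell_half_times()].
#' @return One-row tibble: `n_cells`, `n_converged`, `n_failed`,
#'   `t_half_median`, `t_half_q25`, `t_half_q75`, `t_half_mean`, `t_half_sd`.
#' @export
fit_summary <- function(fits) {
  ok <- dplyr::filter(fits, .data$converged)
  tibble(
    n_cells = nrow(fits),
    n_converged = nrow(ok),
    n_failed = nrow(fits) - nrow(ok),
    t_half_median = median(ok$t_half),
    t_half_q25 = quantile(ok$t_half, 0.25, names = FALSE),
    t_half_q75 = quantile(ok$t_half, 0.75, names = FALSE),
    t_half_mean = mean(ok$t_half),
    t_half_sd = sd(ok$t_half)
  )
}

#' Half-time of the cell-averaged profile
#'
#' For weak signals (endogenous GFP), single-cell fits are unreliable; the net
#' traces are instead averaged pointwise across cells and the initial
#' `window_s` seconds (45 s by default) of the average profile are fitted
#' once.
#'
#' @param traces Net trace tibble (one channel, >= 2 cells) whose time axis
#'   covers at least `window_s`.
#' @param window_s Fit window in seconds (default 45).
#' @return A `recruitment_fit`.
#' @export
average_profile_half_time <- function(traces, window_s = 45) {
  assert_trace_table(traces)
  if (n_distinct(traces$roi_id) < 2L) abort("Need at least 2 cells to average.")
  if (max(traces$time_s) < window_s) {
    abort(sprintf("Traces cover %.3g s, less than the %.3g s fit window.",
                  max(traces$time_s), window_s))
  }
  avg <- traces %>%
    group_by(.data$frame) %>%
    summarise(time_s = .data$time_s[1], value = mean(.data$value), .groups = "drop") %>%
    arrange(.data$time_s)
  fit_saturating_exponential(avg$time_s, avg$value, normalize = TRUE,
                             window_s = window_s)
}

#' Cumulative signal per cell
#'
#' Sums each net trace over all its frames. These per-cell scalars are the
#' inputs to rank-based group comparisons between optogenetic and control
#' populations (normality screening and the tests themselves are delegated to
#' standard implementations such as [stats::kruskal.test()]).
#'
#' @param traces Net trace tibble.
#' @return Tibble: `roi_id` (plus `population` if present), `cumulative`.
#' @export
cumulative_signal <- function(traces) {
  assert_trace_table(traces)
  if ("state" %in% names(traces) && !all(traces$state == "net")) {
    abort("cumulative_signal() expects net traces (state = \"net\").")
  }
  traces %>%
    group_by(dplyr::across(dplyr::any_of(c("roi_id", "cell_id", "population",
                                           "channel")))) %>%
    summarise(cumulative = sum(.data$value), .groups = "drop")
}
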