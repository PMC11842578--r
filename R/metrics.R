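#' Injection efficiency
#'
#' Total task time divided by the number of cells attempted.
#'
#' @param t_tim Total time, s.
#' @param n_tot Number of cells attempted (>= 1).
#' @return Seconds per cell.
#' @examples
#' injection_efficiency(2000, 100) # 20 s/cell
#' @export
injection_efficiency <- function(t_tim, n_tot) {
  if (any(n_tot < 1)) abort("`n_tot` must be >= 1.")
  if (any(t_tim < 0)) abort("`t_tim` must be >= 0.")
  t_tim / n_tot
}

#' Puncture success rate
#'
#' Punctured cells as a percentage of attempted cells.
#'
#' @param n_puc Cells successfully punctured.
#' @param n_tot Cells attempted (>= 1).
#' @return Percentage in \[0, 100\].
#' @export
puncture_success_rate <- function(n_puc, n_tot) {
  if (any(n_tot < 1)) abort("`n_tot` must be >= 1.")
  if (any(n_puc > n_tot)) abort("`n_puc` cannot exceed `n_tot`.")
  if (any(n_puc < 0)) abort("`n_puc` must be >= 0.")
  n_puc / n_tot * 100
}

#' Cell survival rate
#'
#' Successfully punctured cells that hatch into larvae, as a percentage.
#' The stated definition divides by the number punctured
#' (`denominator = "punctured"`, the default); some comparative reports
#' divide by the number attempted instead, which
#' `denominator = "total"` reproduces (requires `n_tot`).
#'
#' @param n_sur Punctured cells that survived.
#' @param n_puc Cells successfully punctured (>= 1 for the default
#'   denominator).
#' @param denominator `"punctured"` or `"total"`.
#' @param n_tot Cells attempted; only used with `denominator = "total"`.
#' @return Percentage in \[0, 100\].
#' @examples
#' survival_rate(84, 100) # 84
#' survival_rate(33, 46) # 71.7
#' survival_rate(33, 46, denominator = "total", n_tot = 50) # 66
#' @export
survival_rate <- function(n_sur, n_puc,
                          denominator = c("punctured", "total"),
                          n_tot = NULL) {
  denominator <- match.arg(denominator)
  if (any(n_sur > n_puc)) abort("`n_sur` cannot exceed `n_puc`.")
  if (any(n_sur < 0)) abort("`n_sur` must be >= 0.")
  if (denominator == "punctured") {
    if (any(n_puc < 1)) abort("`n_puc` must be >= 1.")
    return(n_sur / n_puc * 100)
  }
  if (is.null(n_tot)) abort("`n_tot` is required with denominator = \"total\".")
  if (any(n_tot < 1)) abort("`n_tot` must be >= 1.")
  n_sur / n_tot * 100
}

#' Batch performance metrics report
#'
#' Computes the three batch metrics from raw counters or from a
#' [run_batch()] result, echoing the inputs.
#'
#' @param x A [run_batch()] result, or `NULL` when counters are given
#'   directly.
#' @param n_tot,n_puc,n_sur,t_tim Raw counters (ignored when `x` is a
#'   batch result).
#' @param denominator Survival-rate denominator convention, see
#'   [survival_rate()].
#' @param method Optional label for comparison tables.
#' @return A one-row tibble of class `metrics_report` with the counters
#'   and `efficiency_s_per_cell`, `puncture_rate_pct`,
#'   `survival_rate_pct`.
#' @examples
#' batch_metrics(n_tot = 100, n_puc = 100, n_sur = 84, t_tim = 2000)
#' @export
batch_metrics <- function(x = NULL, n_tot = NULL, n_puc = NULL, n_sur = NULL,
                          t_tim = NULL,
                          denominator = c("punctured", "total"),
                          method = NA_character_) {
  denominator <- match.arg(denominator)
  if (!is.null(x)) {
    stopifnot(inherits(x, "batch_result"))
    n_tot <- x$n_tot; n_puc <- x$n_puc; n_sur <- x$n_sur; t_tim <- x$t_tim_s
  }
  out <- tibble(
    method = method, n_tot = n_tot, n_puc = n_puc, n_sur = n_sur,
    t_tim_s = t_tim,
    efficiency_s_per_cell = injection_efficiency(t_tim, n_tot),
    puncture_rate_pct = puncture_success_rate(n_puc, n_tot),
    survival_rate_pct = survival_rate(n_sur, n_puc,
                                      denominator = denominator,
                                      n_tot = n_tot)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Compare two metrics reports
#'
#' Per-metric differences `b - a` in native units (seconds per cell for
#' the efficiency, percentage points for the rates). Antisymmetric:
#' swapping the arguments negates every difference.
#'
#' @param a,b One-row [batch_metrics()] reports.
#' @return A tibble with columns `metric`, `value_a`, `value_b`,
#'   `difference`.
#' @export
compare_methods <- function(a, b) {
  stopifnot(inherits(a, "metrics_report"), inherits(b, "metrics_report"))
  metrics <- c("efficiency_s_per_cell", "puncture_rate_pct",
               "survival_rate_pct")
  tibble(
    metric = metrics,
    value_a = purrr::map_dbl(metrics, ~ a[[.x]]),
    value_b = purrr::map_dbl(metrics, ~ b[[.x]]),
    difference = purrr::map_dbl(metrics, ~ b[[.x]] - a[[.x]])
  )
}

#' Summarise positioning errors in consecutive groups
#'
#' Splits the error samples into consecutive groups of `group_size` and
#' reports, per group, the first and third quartiles (type-7 linear
#' interpolation), median, mean and the points flagged as outliers by the
#' 1.5 x IQR whisker rule.
#'
#' @param samples Positioning-error samples, um.
#' @param group_size Samples per group (the last group may be shorter).
#' @return A tibble of class `error_summary`: `group`, `n`, `q1`,
#'   `median`, `q3`, `mean` and a list-column `outliers`.
#' @export
summarize_positioning_errors <- function(samples, group_size = 10) {
  if (!length(samples)) abort("`samples` must be non-empty.")
  if (group_size < 1) abort("`group_size` must be >= 1.")
  grp <- (seq_along(samples) - 1L) %/% as.integer(group_size) + 1L
  out <- tibble(value = as.numeric(samples), group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      mean = mean(.data$value),
      outliers = list({
        iqr <- quantile(.data$value, 0.75, type = 7, names = FALSE) -
          quantile(.data$value, 0.25, type = 7, names = FALSE)
        lo <- quantile(.data$value, 0.25, type = 7, names = FALSE) - 1.5 * iqr
        hi <- quantile(.data$value, 0.75, type = 7, names = FALSE) + 1.5 * iqr
        .data$value[.data$value < lo | .data$value > hi]
      }),
      .groups = "drop"
    )
  class(out) <- c("error_summary", class(out))
  out
}
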