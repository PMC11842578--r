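#' Proportional-derivative controller gains
#'
#' @param kp Proportional gain (>= 0).
#' @param kd Derivative gain (>= 0).
#' @param output_limit Saturation bound on the magnitude of the controller
#'   output (actuator pulse rate); the control law itself is unbounded, so
#'   a finite limit keeps the simulated actuator realistic.
#' @return An object of class `pd_gains`.
#' @export
pd_gains <- function(kp, kd = 0, output_limit = 2e4) {
  stop_if_not_number(kp, "kp")
  stop_if_not_number(kd, "kd")
  stop_if_not_number(output_limit, "output_limit", positive = TRUE,
                     finite = FALSE)
  if (kp < 0 || kd < 0) abort("gains must be non-negative.")
  structure(list(kp = kp, kd = kd, output_limit = output_limit),
            class = "pd_gains")
}

#' One discrete PD control step
#'
#' `u = kp * error + kd * (error - prev_error) / dt`, clipped to
#' `+/- output_limit`. The derivative is a backward difference on the
#' sampled error.
#'
#' @param error Current position error.
#' @param prev_error Error at the previous sample.
#' @param dt Sample interval, s (> 0).
#' @param gains A [pd_gains()].
#' @return Control output `u` (pulse rate).
#' @export
pd_step <- function(error, prev_error, dt, gains) {
  stopifnot(inherits(gains, "pd_gains"))
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be > 0.")
  u <- gains$kp * error + gains$kd * (error - prev_error) / dt
  pmin(pmax(u, -gains$output_limit), gains$output_limit)
}

#' Two-speed puncture schedule
#'
#' The needle advances fast (`v_fast`) from its start position to the
#' rupture position, then slow (`v_slow`) toward the yolk centre. The
#' shared boundary belongs to the fast interval: the speed drops only
#' strictly after rupture.
#'
#' @param v_fast Speed before membrane rupture, um/s.
#' @param v_slow Speed after rupture, um/s.
#' @param s_start Needle start position along the insertion axis, um.
#' @param s_pierce Rupture position, um.
#' @param s_target Yolk-centre position, um.
#' @return An object of class `speed_schedule`.
#' @export
speed_schedule <- function(v_fast = 200, v_slow = 60, s_start = 0,
                           s_pierce = 500, s_target = 800) {
  if (v_fast <= 0 || v_slow <= 0) abort("speeds must be > 0.")
  if (!(s_start < s_pierce && s_pierce <= s_target)) {
    abort("positions must satisfy s_start < s_pierce <= s_target.")
  }
  structure(list(v_fast = v_fast, v_slow = v_slow, s_start = s_start,
                 s_pierce = s_pierce, s_target = s_target),
            class = "speed_schedule")
}

#' Commanded needle speed at a position
#'
#' @param s_n Needle position, um; must lie in
#'   `[s_start, s_target]`.
#' @param sched A [speed_schedule()].
#' @return Speed, um/s. Vectorised over `s_n`.
#' @export
scheduled_speed <- function(s_n, sched) {
  stopifnot(inherits(sched, "speed_schedule"))
  if (any(s_n < sched$s_start | s_n > sched$s_target)) {
    abort("`s_n` outside the [s_start, s_target] range.")
  }
  ifelse(s_n <= sched$s_pierce, sched$v_fast, sched$v_slow)
}

#' Expected force state of the sensor at a needle position
#'
#' Three-state force model of the puncture: a quiescent baseline before
#' the rupture position, the force maximum exactly at rupture, and the
#' post-rupture baseline beyond it.
#'
#' @inheritParams scheduled_speed
#' @return One of `"pre_rupture"`, `"at_rupture"`, `"post_rupture"` per
#'   position (character vector).
#' @export
classify_force_state <- function(s_n, sched) {
  stopifnot(inherits(sched, "speed_schedule"))
  if (any(s_n < sched$s_start | s_n > sched$s_target)) {
    abort("`s_n` outside the [s_start, s_target] range.")
  }
  dplyr::case_when(
    s_n < sched$s_pierce ~ "pre_rupture",
    s_n == sched$s_pierce ~ "at_rupture",
    TRUE ~ "post_rupture"
  )
}

#' Construct a force trace
#'
#' A force trace is a tibble of uniformly sampled 3-D tip forces with the
#' derived transverse and total magnitudes, optionally annotated with the
#' ground-truth rupture sample.
#'
#' @param time_s Strictly increasing, uniformly spaced sample times, s.
#' @param fx,fy,fz Force components per sample, mN.
#' @param rupture_index Optional ground-truth rupture sample index.
#' @return A tibble of class `force_trace` with columns `time_s`, `fx_mN`,
#'   `fy_mN`, `fz_mN`, `ft_mN`, `f_total_mN` and attribute
#'   `rupture_index`.
#' @export
force_trace <- function(time_s, fx, fy, fz, rupture_index = NULL) {
  n <- length(time_s)
  if (n < 1L || length(fx) != n || length(fy) != n || length(fz) != n) {
    abort("components must have the same positive length as `time_s`.")
  }
  if (n > 1L) {
    dts <- diff(time_s)
    if (any(dts <= 0) ||
        max(abs(dts - dts[1])) > 1e-9 * max(dts[1], 1e-12)) {
      abort("`time_s` must be strictly increasing and uniformly spaced.")
    }
  }
  if (!is.null(rupture_index)) {
    if (rupture_index < 1L || rupture_index > n) {
      abort("`rupture_index` outside the trace.")
    }
    rupture_index <- as.integer(rupture_index)
  }
  out <- dplyr::bind_cols(tibble(time_s = time_s), compose_force(fx, fy, fz))
  attr(out, "rupture_index") <- rupture_index
  class(out) <- c("force_trace", class(out))
  out
}

#' Ground-truth rupture annotation of a trace
#'
#' @param trace A [force_trace()].
#' @return The annotated rupture sample index, or `NULL`.
#' @export
rupture_annotation <- function(trace) attr(trace, "rupture_index")

#' Detect the membrane-rupture event in a force trace
#'
#' The rupture signature is a sharp jump: the total force rises to a peak
#' and collapses. The detector tracks the running maximum of the total
#' force; it fires at the first sample where that maximum has exceeded
#' `min_peak` and the current force has fallen below
#' `(1 - min_drop_frac)` times it within `window` samples of the peak.
#' Absence of an event is a valid result (`NULL`).
#'
#' @param trace A [force_trace()] (or any tibble with `f_total_mN`).
#' @param min_peak Minimum peak force to arm the detector, mN.
#' @param min_drop_frac Required fractional drop from the running peak,
#'   in (0, 1\].
#' @param window Maximum samples between the peak and the drop.
#' @return A `puncture_event` (list with `rupture_index`, `detect_index`,
#'   `peak_force`, `baseline_before`, `baseline_after`), or `NULL` when no
#'   event qualifies. `rupture_index` is the sample of the running peak —
#'   the rupture instant; `detect_index` is where the drop criterion was
#'   met.
#' @export
detect_puncture <- function(trace, min_peak = 1, min_drop_frac = 0.5,
                            window = 50) {
  if (!nrow(trace)) abort("`trace` is empty.")
  if (min_drop_frac <= 0 || min_drop_frac > 1) {
    abort("`min_drop_frac` must be in (0, 1].")
  }
  f <- trace$f_total_mN
  m <- cummax(f)
  # index of the running maximum (latest sample attaining it)
  argmax <- cummax(seq_along(f) * (f >= m))
  hit <- which(m >= min_peak &
                 f <= (1 - min_drop_frac) * m &
                 (seq_along(f) - argmax) <= window)
  if (!length(hit)) return(NULL)
  j <- hit[1]
  peak_i <- argmax[j]
  pre <- which(f > min_peak)[1]
  baseline_before <- if (!is.na(pre) && pre > 1L) median(f[seq_len(pre - 1L)])
                     else f[1]
  baseline_after <- median(f[j:min(j + window, length(f))])
  structure(
    list(rupture_index = peak_i, detect_index = j, peak_force = m[j],
         baseline_before = baseline_before, baseline_after = baseline_after),
    class = "puncture_event"
  )
}

#' @export
print.puncture_event <- function(x, ...) {
  cat(sprintf(
    "<puncture_event> peak %.3f mN at sample %d (detected at %d); baselines %.3f -> %.3f mN\n",
    x$peak_force, x$rupture_index, x$detect_index, x$baseline_before,
    x$baseline_after))
  invisible(x)
}

#' @method tidy puncture_event
#' @export
tidy.puncture_event <- function(x, ...) {
  tibble(rupture_index = x$rupture_index, detect_index = x$detect_index,
         peak_force_mN = x$peak_force,
         baseline_before_mN = x$baseline_before,
         baseline_after_mN = x$baseline_after)
}

#' Read or write a force trace CSV
#'
#' Columns `time_s`, `fx_mN`, `fy_mN`, `fz_mN`; the transverse and total
#' magnitudes are derived on load.
#'
#' @param path File path.
#' @return `read_force_trace()` returns a [force_trace()].
#' @export
read_force_trace <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("time_s", "fx_mN", "fy_mN", "fz_mN")
  if (!all(needed %in% names(raw))) {
    abort(paste("force trace must have columns", toString(needed)))
  }
  force_trace(raw$time_s, raw$fx_mN, raw$fy_mN, raw$fz_mN)
}

#' @param trace A [force_trace()].
#' @rdname read_force_trace
#' @export
write_force_trace <- function(trace, path) {
  readr::write_csv(trace[, c("time_s", "fx_mN", "fy_mN", "fz_mN")], path)
  invisible(path)
}
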