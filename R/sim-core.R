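#' First-order transport plant
#'
#' Minimal dynamic model of the fluid-driven cell transport: the control
#' pulse rate `u` commands a velocity `gain * u` which the cell approaches
#' with time constant `damping`; position integrates velocity, optionally
#' with process noise.
#'
#' @param gain Velocity per unit control pulse rate, um/s per pulse.
#' @param damping First-order velocity time constant, s.
#' @param process_noise_sd Per-step position noise, um.
#' @param dt Plant integration step, s.
#' @return An object of class `transport_plant`.
#' @export
transport_plant <- function(gain = 1, damping = 0.1, process_noise_sd = 0,
                            dt = 0.01) {
  stop_if_not_number(gain, "gain", positive = TRUE)
  stop_if_not_number(damping, "damping", positive = TRUE)
  stop_if_not_number(dt, "dt", positive = TRUE)
  if (process_noise_sd < 0) abort("`process_noise_sd` must be >= 0.")
  structure(list(gain = gain, damping = damping,
                 process_noise_sd = process_noise_sd, dt = dt),
            class = "transport_plant")
}

#' Perception noise specification
#'
#' Parametric stand-in for the vision pipeline (object detection of the
#' cell centroid and keypoint detection of the needle tip): measurements
#' are the truth plus isotropic Gaussian noise. The default tip noise is
#' calibrated so that the magnitude of the 2-D tip placement error (a
#' Rayleigh variate) has mean 4.95 um, with a 99.9th percentile near
#' 15 um.
#'
#' @param centroid_noise_sd Cell-centroid measurement noise SD, um.
#' @param tip_noise_sd Needle-tip measurement noise SD per image axis, um.
#' @param detect_rate Vision update rate, Hz.
#' @return An object of class `perception_spec`.
#' @export
perception_spec <- function(centroid_noise_sd = 2,
                            tip_noise_sd = 4.95 / sqrt(pi / 2),
                            detect_rate = 15) {
  if (centroid_noise_sd < 0 || tip_noise_sd < 0) {
    abort("noise SDs must be >= 0.")
  }
  stop_if_not_number(detect_rate, "detect_rate", positive = TRUE)
  structure(list(centroid_noise_sd = centroid_noise_sd,
                 tip_noise_sd = tip_noise_sd, detect_rate = detect_rate),
            class = "perception_spec")
}

#' Observe a true position through the noisy perception stub
#'
#' @param truth True position(s), um.
#' @param noise_sd Measurement noise SD, um.
#' @param seed Optional scoped seed.
#' @return Measured position(s), um.
#' @export
perception_observe <- function(truth, noise_sd, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (noise_sd == 0) return(truth)
  with_seed_maybe(seed, truth + rnorm(length(truth), sd = noise_sd))
}

#' Draw needle-tip placement errors
#'
#' Magnitude of the 2-D tip placement error: `sqrt(ex^2 + ey^2)` with
#' independent Gaussian components of SD `tip_noise_sd` (Rayleigh
#' distributed).
#'
#' @param n Number of draws.
#' @param spec A [perception_spec()].
#' @param seed Optional scoped seed.
#' @return Numeric vector of error magnitudes, um.
#' @export
tip_placement_error <- function(n, spec = perception_spec(), seed = NULL) {
  stopifnot(inherits(spec, "perception_spec"))
  with_seed_maybe(seed, sqrt(rnorm(n, sd = spec$tip_noise_sd)^2 +
                               rnorm(n, sd = spec$tip_noise_sd)^2))
}

#' A single embryo instance for trace synthesis
#'
#' @param radius Embryo radius, um.
#' @param membrane_rupture_force Total tip force at membrane rupture, mN.
#' @param stiffness Force per unit indentation before rupture, mN/um.
#' @param peak_transverse,peak_axial Transverse and axial components used
#'   to orient the peak force (only their ratio matters; defaults 3.1 and
#'   2.4 mN, the prototype's measured split).
#' @return An object of class `cell_instance`.
#' @export
cell_instance <- function(radius = 500, membrane_rupture_force = 3.9,
                          stiffness = 0.02, peak_transverse = 3.1,
                          peak_axial = 2.4) {
  stop_if_not_number(radius, "radius", positive = TRUE)
  stop_if_not_number(membrane_rupture_force, "membrane_rupture_force",
                     positive = TRUE)
  stop_if_not_number(stiffness, "stiffness", positive = TRUE)
  if (peak_transverse < 0 || peak_axial < 0 ||
      peak_transverse + peak_axial == 0) {
    abort("peak components must be non-negative and not both zero.")
  }
  structure(list(radius = radius,
                 membrane_rupture_force = membrane_rupture_force,
                 stiffness = stiffness, peak_transverse = peak_transverse,
                 peak_axial = peak_axial),
            class = "cell_instance")
}

#' Simulate PD-controlled cell transport
#'
#' Discrete-time closed loop: at each vision frame the cell position is
#' observed through the perception stub, the PD controller computes the
#' pump pulse rate from the position error, and the first-order plant
#' integrates under the held command until the next frame. Settling is
#' declared at the first time after which the true error magnitude stays
#' below `tol` for the rest of the horizon; a run that never settles is
#' reported with `settled = FALSE`, not an error.
#'
#' @param target,start Target and initial positions, um.
#' @param plant A [transport_plant()].
#' @param gains A [pd_gains()]; defaults `pd_gains(2, 0.05)` give an
#'   overdamped loop settling a 1 mm step in about 2 s.
#' @param perception A [perception_spec()] (its `centroid_noise_sd` and
#'   `detect_rate` are used).
#' @param tol Settling tolerance on the position error, um.
#' @param max_t Simulation horizon, s.
#' @param seed Optional scoped seed for measurement/process noise.
#' @return A list of class `transport_sim`: `trajectory` (tibble with
#'   `time_s`, `x_um`, `measured_um`, `error_um`, `u`), `settle_time_s`
#'   (NA when not settled), `settled`.
#' @export
simulate_transport <- function(target, start = 0, plant = transport_plant(),
                               gains = pd_gains(2, 0.05),
                               perception = perception_spec(),
                               tol = 5, max_t = 10, seed = NULL) {
  stopifnot(inherits(plant, "transport_plant"),
            inherits(gains, "pd_gains"),
            inherits(perception, "perception_spec"))
  if (tol <= 0) abort("`tol` must be > 0.")
  with_seed_maybe(seed, {
    dt_frame <- 1 / perception$detect_rate
    n_sub <- max(1L, round(dt_frame / plant$dt))
    dt_sub <- dt_frame / n_sub
    n_frames <- ceiling(max_t / dt_frame)
    x <- start
    v <- 0
    e_prev <- target - start
    rows <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      measured <- perception_observe(x, perception$centroid_noise_sd)
      e <- target - measured
      u <- pd_step(e, e_prev, dt_frame, gains)
      e_prev <- e
      for (s in seq_len(n_sub)) {
        v <- v + dt_sub * (plant$gain * u - v) / plant$damping
        x <- x + dt_sub * v
        if (plant$process_noise_sd > 0) {
          x <- x + rnorm(1, sd = plant$process_noise_sd)
        }
      }
      rows[[k]] <- c(time_s = k * dt_frame, x_um = x, measured_um = measured,
                     error_um = target - x, u = u)
    }
    traj <- as_tibble(do.call(rbind, rows))
    bad <- which(abs(traj$error_um) >= tol)
    settle_idx <- if (!length(bad)) 1L else if (max(bad) < nrow(traj))
      max(bad) + 1L else NA_integer_
    settled <- !is.na(settle_idx)
    settle_time <- if (!settled) NA_real_
                   else if (abs(target - start) < tol) 0
                   else traj$time_s[settle_idx]
    structure(
      list(trajectory = traj, settle_time_s = settle_time,
           settled = settled),
      class = "transport_sim"
    )
  })
}

#' Synthesise a puncture force trace
#'
#' Builds the canonical rupture morphology at the FBG decoder's sampling
#' rate: quiescent baseline while the needle approaches at the fast speed,
#' a force rising linearly with indentation up to the membrane rupture
#' force, a collapse to the post-rupture baseline within a few samples,
#' and a residual slow-advance segment to the yolk centre. The peak force
#' is split between transverse and axial channels in the cell's configured
#' ratio so the Euclidean norm of the components equals the total force.
#' Gaussian noise is added per component; the true rupture sample is
#' annotated.
#'
#' @param cell A [cell_instance()].
#' @param sched A [speed_schedule()].
#' @param noise_sd Per-component force noise SD, mN.
#' @param sample_rate Sampling rate, Hz (default 1000, the FBG decoder
#'   rate).
#' @param baseline_pre,baseline_post Total-force baselines before contact
#'   and after rupture, mN.
#' @param collapse_samples Samples over which the force collapses at
#'   rupture (<= 5).
#' @param tail_s Dwell recorded after reaching the target, s.
#' @param seed Optional scoped seed.
#' @return A [force_trace()] annotated with the rupture index.
#' @export
synth_puncture_trace <- function(cell = cell_instance(),
                                 sched = speed_schedule(),
                                 noise_sd = 0.05, sample_rate = 1000,
                                 baseline_pre = 0, baseline_post = 0.1,
                                 collapse_samples = 3, tail_s = 0.2,
                                 seed = NULL) {
  stopifnot(inherits(cell, "cell_instance"), inherits(sched, "speed_schedule"))
  stop_if_not_number(sample_rate, "sample_rate", positive = TRUE)
  if (collapse_samples < 1 || collapse_samples > 5) {
    abort("`collapse_samples` must be in 1..5.")
  }
  indent <- cell$membrane_rupture_force / cell$stiffness
  s_contact <- sched$s_pierce - indent
  if (s_contact <= sched$s_start) {
    abort("indentation depth exceeds the fast-approach distance; increase stiffness or the approach range.")
  }
  dt <- 1 / sample_rate
  t_contact <- (s_contact - sched$s_start) / sched$v_fast
  t_pierce <- t_contact + indent / sched$v_fast
  t_slow <- (sched$s_target - sched$s_pierce) / sched$v_slow
  t_end <- t_pierce + collapse_samples * dt + t_slow + tail_s
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  i_pierce <- which(times >= t_pierce)[1]
  total <- numeric(n) + baseline_pre
  rising <- times > t_contact & seq_len(n) <= i_pierce
  total[rising] <- baseline_pre +
    cell$stiffness * sched$v_fast * (times[rising] - t_contact)
  total[i_pierce] <- cell$membrane_rupture_force
  i_post <- min(i_pierce + collapse_samples, n)
  if (i_post > i_pierce) {
    ramp <- seq(cell$membrane_rupture_force, baseline_post,
                length.out = i_post - i_pierce + 1L)
    total[(i_pierce + 1L):i_post] <- ramp[-1]
  }
  if (i_post < n) total[(i_post + 1L):n] <- baseline_post
  unit <- c(cell$peak_transverse, cell$peak_axial) /
    sqrt(cell$peak_transverse^2 + cell$peak_axial^2)
  fx <- total * unit[1]
  fy <- numeric(n)
  fz <- total * unit[2]
  if (noise_sd > 0) {
    noise <- with_seed_maybe(seed, matrix(rnorm(3L * n, sd = noise_sd), ncol = 3))
    fx <- fx + noise[, 1]
    fy <- fy + noise[, 2]
    fz <- fz + noise[, 3]
  }
  force_trace(times, fx, fy, fz, rupture_index = i_pierce)
}

#' Default configuration of the injection simulator
#'
#' Bundles every sub-model of the digital twin with defaults calibrated to
#' the prototype's operating point: a full cycle takes about 20 s per cell
#' under the default timing budget, puncture detection is essentially
#' certain at the default trace noise, and the survival model averages
#' 84% over the tip placement error distribution.
#'
#' @param calibration An [fbg_calibration()].
#' @param mechanics A [cell_system_params()].
#' @param cell A [cell_instance()].
#' @param schedule A [speed_schedule()].
#' @param gains Transport [pd_gains()].
#' @param plant A [transport_plant()].
#' @param perception A [perception_spec()].
#' @param detector Detector thresholds: list with `min_peak` (mN),
#'   `min_drop_frac`, `window` (samples).
#' @param trace_noise_sd Force-trace noise SD, mN.
#' @param sample_rate Force sampling rate, Hz.
#' @param transport List: `start_um`, `target_um`, `tol_um`, `max_t_s`.
#' @param hold List: `pressure_margin` (applied / critical) and `hold_s`.
#' @param timing List of fixed phase durations, s: `feed_s` (pump loading
#'   before vision lock), `inject_s`, `recycle_s`.
#' @param survival List: `mode` (`"logistic"` or `"fixed"`), `prob` (fixed
#'   mode), `intercept` and `slope` (logistic mode: success probability
#'   `plogis(intercept - slope * tip_error_um)`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(calibration = reference_calibration(),
                       mechanics = cell_system_params(),
                       cell = cell_instance(),
                       schedule = speed_schedule(),
                       gains = pd_gains(2, 0.05),
                       plant = transport_plant(),
                       perception = perception_spec(),
                       detector = list(min_peak = 1, min_drop_frac = 0.5,
                                       window = 50),
                       trace_noise_sd = 0.05,
                       sample_rate = 1000,
                       transport = list(start_um = 0, target_um = 1000,
                                        tol_um = 5, max_t_s = 10),
                       hold = list(pressure_margin = 1.2, hold_s = 2),
                       timing = list(feed_s = 3, inject_s = 2.5,
                                     recycle_s = 2.5),
                       survival = list(mode = "logistic", prob = 0.84,
                                       intercept = 2.4523, slope = 0.15)) {
  structure(
    list(calibration = calibration, mechanics = mechanics, cell = cell,
         schedule = schedule, gains = gains, plant = plant,
         perception = perception, detector = detector,
         trace_noise_sd = trace_noise_sd, sample_rate = sample_rate,
         transport = transport, hold = hold, timing = timing,
         survival = survival),
    class = "sim_config"
  )
}

draw_survival <- function(punctured, tip_error, survival) {
  if (!punctured) return(FALSE)
  p <- switch(survival$mode,
    fixed = survival$prob,
    logistic = plogis(survival$intercept - survival$slope * tip_error),
    abort("unknown survival mode.")
  )
  runif(1) < p
}

#' Run one injection cycle
#'
#' Executes the per-cell state machine: transport to the holding port
#' under PD control, suction holding checked against the critical holding
#' pressure, two-speed puncture with force-jump detection, injection (only
#' when the rupture was detected), and recycling. All randomness derives
#' from `seed`; a phase timeout marks the cycle failed with the phase
#' named rather than raising.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param keep_trace Keep the synthesised force trace in the result?
#' @return A list of class `cycle_result` with logical outcomes,
#'   per-phase timings (`phase_s`, a named numeric summing to
#'   `t_total_s`), `tip_error_um`, the detected event and optionally the
#'   trace.
#' @export
run_injection_cycle <- function(config = sim_config(), seed = NULL,
                                keep_trace = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else
    lapply(1:4, function(k) derive_seed(seed, k, stride = 104729))
  tr <- simulate_transport(
    target = config$transport$target_um, start = config$transport$start_um,
    plant = config$plant, gains = config$gains,
    perception = config$perception, tol = config$transport$tol_um,
    max_t = config$transport$max_t_s, seed = seeds[[1]]
  )
  failed_phase <- NA_character_
  phase <- c(transport = NA_real_, hold = 0, puncture = 0, inject = 0,
             recycle = 0)
  phase[["transport"]] <- config$timing$feed_s +
    (if (tr$settled) tr$settle_time_s else config$transport$max_t_s)
  punctured <- FALSE
  survived <- FALSE
  tip_error <- NA_real_
  event <- NULL
  trace <- NULL
  if (!tr$settled) {
    failed_phase <- "transport"
  } else {
    p_crit <- critical_holding_pressure(config$mechanics)
    held <- config$hold$pressure_margin * p_crit >= p_crit
    phase[["hold"]] <- config$hold$hold_s
    if (!held) {
      failed_phase <- "hold"
    } else {
      trace <- synth_puncture_trace(
        cell = config$cell, sched = config$schedule,
        noise_sd = config$trace_noise_sd,
        sample_rate = config$sample_rate, seed = seeds[[2]]
      )
      phase[["puncture"]] <- max(trace$time_s)
      event <- detect_puncture(trace,
                               min_peak = config$detector$min_peak,
                               min_drop_frac = config$detector$min_drop_frac,
                               window = config$detector$window)
      punctured <- !is.null(event)
      tip_error <- tip_placement_error(1, config$perception,
                                       seed = seeds[[3]])
      if (punctured) {
        phase[["inject"]] <- config$timing$inject_s
      }
      phase[["recycle"]] <- config$timing$recycle_s
      survived <- with_seed_maybe(
        seeds[[4]], draw_survival(punctured, tip_error, config$survival))
    }
  }
  structure(
    list(punctured = punctured, survived = survived,
         tip_error_um = tip_error, phase_s = phase,
         t_total_s = sum(phase), failed_phase = failed_phase,
         event = event, trace = if (keep_trace) trace else NULL),
    class = "cycle_result"
  )
}

#' Run a batch of injection cycles
#'
#' Runs `n_cells` independent cycles with per-cell random streams derived
#' from the root seed by a fixed splitting rule, and aggregates the batch
#' counters: cells attempted (`n_tot`), successfully punctured (`n_puc`,
#' also the workflow's injected counter M), surviving (`n_sur`) and total
#' time (`t_tim_s`). The counters always satisfy
#' `n_sur <= n_puc <= n_tot`.
#'
#' @param n_cells Number of cells to inject (>= 1).
#' @param config A [sim_config()].
#' @param seed Optional integer root seed; the same seed reproduces the
#'   batch exactly.
#' @return An object of class `batch_result`: counters plus a `cycles`
#'   tibble (one row per cell with outcomes and per-phase timings).
#' @export
run_batch <- function(n_cells, config = sim_config(), seed = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1) abort("`n_cells` must be >= 1.")
  n_cells <- as.integer(n_cells)
  cycles <- purrr::map(seq_len(n_cells), function(i) {
    run_injection_cycle(config,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, i))
  })
  cyc <- purrr::map_dfr(seq_along(cycles), function(i) {
    x <- cycles[[i]]
    tibble(
      cell = i, punctured = x$punctured, survived = x$survived,
      tip_error_um = x$tip_error_um,
      t_transport_s = x$phase_s[["transport"]],
      t_hold_s = x$phase_s[["hold"]],
      t_puncture_s = x$phase_s[["puncture"]],
      t_inject_s = x$phase_s[["inject"]],
      t_recycle_s = x$phase_s[["recycle"]],
      t_total_s = x$t_total_s,
      failed_phase = x$failed_phase,
      peak_force_mN = if (is.null(x$event)) NA_real_ else x$event$peak_force
    )
  })
  structure(
    list(n_tot = n_cells, n_puc = sum(cyc$punctured),
         n_sur = sum(cyc$survived), t_tim_s = sum(cyc$t_total_s),
         injected_counter = sum(cyc$punctured), seed = seed, cycles = cyc),
    class = "batch_result"
  )
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "<batch_result> %d cells: %d punctured, %d survived, %.1f s total (%.1f s/cell)\n",
    x$n_tot, x$n_puc, x$n_sur, x$t_tim_s, x$t_tim_s / x$n_tot))
  invisible(x)
}

#' @method tidy batch_result
#' @export
tidy.batch_result <- function(x, ...) x$cycles

#' @method glance batch_result
#' @export
glance.batch_result <- function(x, ...) {
  tibble(
    n_tot = x$n_tot, n_puc = x$n_puc, n_sur = x$n_sur, t_tim_s = x$t_tim_s,
    efficiency_s_per_cell = injection_efficiency(x$t_tim_s, x$n_tot),
    puncture_rate_pct = puncture_success_rate(x$n_puc, x$n_tot),
    survival_rate_pct = if (x$n_puc > 0) survival_rate(x$n_sur, x$n_puc)
                        else NA_real_
  )
}

#' Serialise a batch result to canonical JSON
#'
#' Full-precision, deterministic serialisation: identical configuration
#' and seed produce byte-identical JSON.
#'
#' @param batch A [run_batch()] result.
#' @return A JSON string.
#' @export
batch_json <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  doc <- list(
    n_tot = batch$n_tot, n_puc = batch$n_puc, n_sur = batch$n_sur,
    t_tim_s = batch$t_tim_s, injected_counter = batch$injected_counter,
    seed = batch$seed, cycles = batch$cycles
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

#' @param path File path for the JSON report.
#' @rdname batch_json
#' @export
write_batch <- function(batch, path) {
  writeLines(batch_json(batch), path)
  invisible(path)
}
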