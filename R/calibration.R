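#' Decompose a calibration load into Cartesian components
#'
#' A load of magnitude `load_mag` applied at pitch angle `pitch_deg` (alpha)
#' and roll angle `roll_deg` (beta) decomposes as
#' `F_X = F sin(a) cos(b)`, `F_Y = F sin(a) sin(b)`, `F_Z = F cos(a)`.
#' The Euclidean norm of the components equals the applied magnitude for
#' every angle pair. Vectorised.
#'
#' @param load_mag Applied force magnitude, mN (>= 0).
#' @param pitch_deg Pitch angle alpha, degrees, in \[-90, 90\].
#' @param roll_deg Roll angle beta, degrees, in \[0, 90\].
#' @return A tibble with columns `fx_mN`, `fy_mN`, `fz_mN`.
#' @export
decompose_load <- function(load_mag, pitch_deg, roll_deg) {
  if (any(load_mag < 0)) abort("`load_mag` must be >= 0.")
  if (any(abs(pitch_deg) > 90)) abort("`pitch_deg` must be in [-90, 90].")
  if (any(roll_deg < 0 | roll_deg > 90)) abort("`roll_deg` must be in [0, 90].")
  a <- deg2rad(pitch_deg)
  b <- deg2rad(roll_deg)
  tibble(
    fx_mN = load_mag * sin(a) * cos(b),
    fy_mN = load_mag * sin(a) * sin(b),
    fz_mN = load_mag * cos(a)
  )
}

#' Default pitch/roll/load calibration grid
#'
#' Pitch alpha at 15-degree intervals over +/-(30..90), roll beta at
#' 15-degree intervals over 0..90, and five load magnitudes spanning the
#' 0-10 mN range: 10 x 7 x 5 = 350 grid points.
#'
#' @param pitch_deg,roll_deg,load_mN Grid axes.
#' @return A tibble with one row per grid point (`pitch_deg`, `roll_deg`,
#'   `load_mN`).
#' @export
calibration_grid <- function(pitch_deg = c(-seq(30, 90, by = 15),
                                           seq(30, 90, by = 15)),
                             roll_deg = seq(0, 90, by = 15),
                             load_mN = c(2, 4, 6, 8, 10)) {
  if (!length(pitch_deg) || !length(roll_deg) || !length(load_mN)) {
    abort("grid axes must be non-empty.")
  }
  tidyr::expand_grid(pitch_deg = sort(pitch_deg), roll_deg = roll_deg,
                     load_mN = load_mN)
}

#' Generate a synthetic calibration sweep
#'
#' Applies each grid load through the forward model of a ground-truth
#' calibration and records the four wavelength shifts with i.i.d. Gaussian
#' read noise. Deterministic for a given seed.
#'
#' @param grid A tibble from [calibration_grid()] (or any tibble with
#'   `pitch_deg`, `roll_deg`, `load_mN`).
#' @param truth Ground-truth forward model: an [fbg_calibration()] or a
#'   4x3 forward matrix (see [fbg_response()]).
#' @param noise_sd Wavelength read-noise standard deviation, nm.
#' @param seed Optional integer seed (scoped; the global RNG state is
#'   restored afterwards).
#' @return A tibble with columns `pitch_deg`, `roll_deg`, `load_mN`,
#'   `fx_mN`, `fy_mN`, `fz_mN`, `dlam1_nm` .. `dlam4_nm`.
#' @examples
#' sweep <- generate_sweep(noise_sd = 0, seed = 1)
#' nrow(sweep) # 350
#' @export
generate_sweep <- function(grid = calibration_grid(),
                           truth = reference_calibration(),
                           noise_sd = 0.01, seed = NULL) {
  if (!nrow(grid)) abort("`grid` is empty.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  forces <- decompose_load(grid$load_mN, grid$pitch_deg, grid$roll_deg)
  shifts <- fbg_response(forces, forward = truth)
  if (noise_sd > 0) {
    noise <- with_seed_maybe(seed, matrix(
      rnorm(4L * nrow(grid), sd = noise_sd), ncol = 4))
    shifts <- shifts + noise
  }
  dplyr::bind_cols(grid, forces, shifts)
}

#' Fit the decoding matrices from a calibration sweep
#'
#' Least-squares calibration in two steps, as for any linear multi-axis
#' force sensor: first the 4x3 forward sensitivity matrix is fitted by
#' ordinary least squares of the recorded shifts on the (exactly known)
#' applied force components, then the decoding matrices are its
#' Moore-Penrose pseudoinverse — the axial row acting on the four raw
#' shifts, the transverse 2x3 block acting on the common-mode-rejected
#' shifts of `fiber_subset`. With noiseless data generated from a known
#' model the ground-truth matrices are recovered exactly; fitting the
#' forward map (whose regressors are the designed loads, not the noisy
#' shifts) keeps the axial row identifiable even though pure force loading
#' only excites three of the four shift dimensions.
#'
#' @param sweep A sweep tibble as from [generate_sweep()] (columns
#'   `fx_mN`, `fy_mN`, `fz_mN`, `dlam1_nm` .. `dlam4_nm`).
#' @param fiber_subset Which 3 fibres feed the transverse decoding.
#' @return An [fbg_calibration()] with its `fit` report populated
#'   (see [evaluate_fit()]).
#' @export
fit_calibration <- function(sweep, fiber_subset = 1:3) {
  fcols <- c("fx_mN", "fy_mN", "fz_mN")
  lcols <- paste0("dlam", 1:4, "_nm")
  if (!all(c(fcols, lcols) %in% names(sweep))) {
    abort("`sweep` must carry force and wavelength-shift columns.")
  }
  f <- as.matrix(sweep[, fcols])   # n x 3
  lam <- as.matrix(sweep[, lcols]) # n x 4
  if (nrow(f) < 3L) abort("need at least 3 samples to fit 3 force axes.")
  qrf <- qr(f)
  if (qrf$rank < 3L) {
    dead <- fcols[setdiff(1:3, sort(qrf$pivot[seq_len(qrf$rank)]))]
    abort(paste0("singular fit: no excitation on axis ",
                 toString(dead), "."))
  }
  # forward sensitivity: lam ~ f, no intercept (homogeneous linear map)
  G <- t(solve(crossprod(f), crossprod(f, lam))) # 4 x 3
  D <- MASS::ginv(G)                             # 3 x 4 decoder
  a_axi <- D[3, ]
  K <- subset_centering_matrix(as.integer(fiber_subset)) %*% G # 3 x 3, rank 2
  c_tran <- cbind(diag(2), 0) %*% MASS::ginv(K)
  model <- fbg_calibration(c_tran, a_axi, fiber_subset = fiber_subset)
  model$fit <- evaluate_fit(sweep, model)
  model
}

#' Decode forces from a sweep's recorded shifts
#'
#' @param sweep A sweep tibble carrying `dlam1_nm` .. `dlam4_nm`.
#' @param model An [fbg_calibration()].
#' @return A tibble with decoded `fx_hat_mN`, `fy_hat_mN`, `fz_hat_mN`.
#' @export
predict_forces <- function(sweep, model) {
  stopifnot(inherits(model, "fbg_calibration"))
  lam <- as.matrix(sweep[, paste0("dlam", 1:4, "_nm")])
  ds <- lam %*% t(subset_centering_matrix(model$fiber_subset))
  ft <- transverse_force(ds, model)
  tibble(fx_hat_mN = ft$fx_mN, fy_hat_mN = ft$fy_mN,
         fz_hat_mN = axial_force(lam, model))
}

#' Evaluate calibration fit quality
#'
#' Regresses decoded on true force per axis (through the origin, so a
#' perfect sensor gives slope 1), reports the mean absolute decoding error
#' per axis, and bins the residuals by the magnitude of the true force in
#' 1 mN intervals over the 0-10 mN calibration range (10 bins).
#' The report is invariant to sample order.
#'
#' @inheritParams fit_calibration
#' @param model A fitted [fbg_calibration()].
#' @return A list with elements `slopes` (tibble: axis, slope),
#'   `mae` (tibble: axis, mae_mN), `residual_bins` (tibble: axis, bin
#'   midpoint, n, mean and extreme residuals) and `n`.
#' @export
evaluate_fit <- function(sweep, model) {
  pred <- predict_forces(sweep, model)
  truth <- sweep[, c("fx_mN", "fy_mN", "fz_mN")]
  axes <- c("fx", "fy", "fz")
  long <- purrr::map_dfr(seq_along(axes), function(i) {
    tibble(axis = axes[i],
           true_mN = truth[[i]],
           est_mN = pred[[i]])
  })
  slopes <- long |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      slope = sum(.data$est_mN * .data$true_mN) / sum(.data$true_mN^2),
      .groups = "drop"
    )
  mae <- long |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(mae_mN = mean(abs(.data$est_mN - .data$true_mN)),
                     .groups = "drop")
  breaks <- 0:10
  residual_bins <- long |>
    dplyr::mutate(
      residual_mN = .data$est_mN - .data$true_mN,
      bin = cut(pmin(abs(.data$true_mN), 10 - 1e-12), breaks = breaks,
                include.lowest = TRUE, right = FALSE)
    ) |>
    dplyr::group_by(.data$axis, .data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_residual_mN = mean(.data$residual_mN),
      min_residual_mN = suppressWarnings(min(.data$residual_mN)),
      max_residual_mN = suppressWarnings(max(.data$residual_mN)),
      .groups = "drop"
    )
  list(slopes = slopes, mae = mae, residual_bins = residual_bins,
       n = nrow(sweep))
}

#' @method tidy fbg_calibration
#' @export
tidy.fbg_calibration <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::expand_grid(component = "c_tran", row = 1:2, fiber = 1:3) |>
      dplyr::mutate(estimate = as.vector(t(x$c_tran))[
        (row - 1L) * 3L + fiber]),
    tibble(component = "a_axi", row = 1L, fiber = 1:4, estimate = x$a_axi)
  )
}

#' @method glance fbg_calibration
#' @export
glance.fbg_calibration <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(n = NA_integer_))
  }
  wide <- tidyr::pivot_wider(
    dplyr::left_join(x$fit$slopes, x$fit$mae, by = "axis"),
    names_from = "axis", values_from = c("slope", "mae_mN")
  )
  dplyr::mutate(wide, n = x$fit$n)
}

#' Read or write a calibration sweep CSV
#'
#' Columns `pitch_deg`, `roll_deg`, `load_mN`, `fx_mN`, `fy_mN`, `fz_mN`,
#' `dlam1_nm` .. `dlam4_nm`.
#'
#' @param path File path.
#' @return `read_sweep()` returns a tibble.
#' @export
read_sweep <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("pitch_deg", "roll_deg", "load_mN", "fx_mN", "fy_mN", "fz_mN",
              paste0("dlam", 1:4, "_nm"))
  if (!all(needed %in% names(out))) {
    abort(paste("sweep must have columns", toString(needed)))
  }
  out
}

#' @param sweep A sweep tibble.
#' @rdname read_sweep
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(sweep, path)
  invisible(path)
}
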