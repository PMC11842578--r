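#' Fibre Bragg grating specification
#'
#' Describes one FBG written into an optical fibre glued along the injection
#' needle. The reflected (Bragg) wavelength is `2 * effective_index *
#' grating_period`, and its shift under load is linear in strain and
#' temperature change.
#'
#' @param effective_index Effective refractive index of the fibre core
#'   (dimensionless, > 1).
#' @param grating_period Period of the refractive-index modulation, nm.
#' @param strain_coeff Wavelength shift per unit strain, nm per microstrain.
#' @param temp_coeff Wavelength shift per kelvin, nm/K.
#'
#' @return An object of class `grating_spec`.
#' @examples
#' spec <- grating_spec(effective_index = 1.45, grating_period = 535)
#' bragg_wavelength(spec)
#' @export
grating_spec <- function(effective_index = 1.45, grating_period = 535,
                         strain_coeff = 1.2e-3, temp_coeff = 1.0e-2) {
  stop_if_not_number(effective_index, "effective_index")
  stop_if_not_number(grating_period, "grating_period")
  stop_if_not_number(strain_coeff, "strain_coeff")
  stop_if_not_number(temp_coeff, "temp_coeff")
  if (effective_index <= 1) abort("`effective_index` must be > 1.")
  if (grating_period <= 0) abort("`grating_period` must be > 0.")
  structure(
    list(
      effective_index = effective_index,
      grating_period = grating_period,
      strain_coeff = strain_coeff,
      temp_coeff = temp_coeff
    ),
    class = "grating_spec"
  )
}

#' Central Bragg wavelength of a grating
#'
#' @param spec A [grating_spec()].
#' @return Central reflected wavelength, nm.
#' @export
bragg_wavelength <- function(spec) {
  stopifnot(inherits(spec, "grating_spec"))
  2 * spec$effective_index * spec$grating_period
}

#' Wavelength shift under strain and temperature change
#'
#' Linear FBG transduction: `strain_coeff * strain + temp_coeff * temp_change`.
#' Both inputs may be vectors (recycled as usual).
#'
#' @param strain Strain at the grating, microstrain.
#' @param temp_change Temperature change, K.
#' @inheritParams bragg_wavelength
#' @return Wavelength shift(s), nm.
#' @export
wavelength_shift <- function(strain, temp_change = 0, spec = grating_spec()) {
  stopifnot(inherits(spec, "grating_spec"))
  spec$strain_coeff * strain + spec$temp_coeff * temp_change
}

#' Injection-needle geometry for bending-strain transduction
#'
#' Geometry of the glass needle carrying the FBG fibres. A transverse tip
#' force `F` bends the needle and produces a surface strain
#' `F * fbg_distance * tube_radius / (youngs_modulus * inertia_torque)` at
#' the grating position.
#'
#' @param youngs_modulus Young's modulus of the needle, Pa (or any unit
#'   consistent with the others; see [tip_strain()]).
#' @param inertia_torque Second moment of area of the needle cross-section.
#' @param tube_radius Outer radius of the needle tube, mm.
#' @param fbg_distance Distance from the needle tip to the grating, mm.
#'
#' @return An object of class `needle_geometry`.
#' @export
needle_geometry <- function(youngs_modulus, inertia_torque, tube_radius,
                            fbg_distance) {
  for (nm in c("youngs_modulus", "inertia_torque", "tube_radius",
               "fbg_distance")) {
    stop_if_not_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(
      youngs_modulus = youngs_modulus,
      inertia_torque = inertia_torque,
      tube_radius = tube_radius,
      fbg_distance = fbg_distance
    ),
    class = "needle_geometry"
  )
}

#' Bending strain at the grating for a transverse tip force
#'
#' Cantilever bending of the needle:
#' `strain = tip_force * fbg_distance * tube_radius /
#' (youngs_modulus * inertia_torque)`. The caller supplies consistent units;
#' with forces in mN and geometry chosen accordingly the result is in
#' microstrain. Linear in the force, so vectorised over `tip_force`.
#'
#' @param tip_force Force applied at the needle tip (bending-plane
#'   component), mN.
#' @param geom A [needle_geometry()].
#' @return Strain at the FBG, microstrain.
#' @export
tip_strain <- function(tip_force, geom) {
  stopifnot(inherits(geom, "needle_geometry"))
  tip_force * geom$fbg_distance * geom$tube_radius /
    (geom$youngs_modulus * geom$inertia_torque)
}

#' Common-mode rejection across three fibres
#'
#' Subtracts the arithmetic mean of the three wavelength shifts from each,
#' cancelling temperature and axial-strain components shared by all fibres
#' and isolating the bending (differential) signal. The three outputs sum
#' to zero by construction.
#'
#' @param shifts A numeric vector of exactly 3 wavelength shifts (nm), or a
#'   matrix / data frame with 3 columns (one row per time point).
#' @return Same shape as the input: centred shifts, nm.
#' @examples
#' common_mode_reject(c(3, 0, 0))
#' @export
common_mode_reject <- function(shifts) {
  if (is.data.frame(shifts)) shifts <- as.matrix(shifts)
  if (is.matrix(shifts)) {
    if (ncol(shifts) != 3L) abort("`shifts` must have exactly 3 columns.")
    return(shifts - rowMeans(shifts))
  }
  if (!is.numeric(shifts) || length(shifts) != 3L) {
    abort("`shifts` must have exactly 3 entries.")
  }
  shifts - mean(shifts)
}

# fibres sit at 90 degree increments around the needle, counter-clockwise
# viewed from the tip, fibre 1 on +X
fiber_angles_deg <- c(0, 90, 180, 270)

#' FBG force-decoding calibration model
#'
#' Holds the two decoding matrices of the four-fibre sensor: a 2x3 matrix
#' `c_tran` mapping the common-mode-rejected shifts of a three-fibre subset
#' to the transverse force components (F_X, F_Y), and a 1x4 row `a_axi`
#' mapping the four raw shifts to the axial force F_Z. Units are mN of
#' force per nm of shift.
#'
#' @param c_tran Numeric 2x3 matrix, mN/nm.
#' @param a_axi Numeric vector of length 4 (or 1x4 matrix), mN/nm.
#' @param fiber_subset Integer vector of length 3: which fibres feed the
#'   transverse decoding (default fibres 1-3).
#' @param fit Optional fit report as produced by [evaluate_fit()].
#'
#' @return An object of class `fbg_calibration`.
#' @seealso [reference_calibration()], [fit_calibration()]
#' @export
fbg_calibration <- function(c_tran, a_axi, fiber_subset = 1:3, fit = NULL) {
  c_tran <- as.matrix(c_tran)
  if (!all(dim(c_tran) == c(2L, 3L))) abort("`c_tran` must be 2x3.")
  a_axi <- as.numeric(a_axi)
  if (length(a_axi) != 4L) abort("`a_axi` must have 4 entries.")
  fiber_subset <- as.integer(fiber_subset)
  if (length(fiber_subset) != 3L || anyDuplicated(fiber_subset) ||
      any(fiber_subset < 1L | fiber_subset > 4L)) {
    abort("`fiber_subset` must be 3 distinct fibre indices in 1..4.")
  }
  if (!all(is.finite(c_tran)) || !all(is.finite(a_axi))) {
    abort("calibration coefficients must be finite.")
  }
  structure(
    list(c_tran = c_tran, a_axi = a_axi, fiber_subset = fiber_subset,
         fit = fit),
    class = "fbg_calibration"
  )
}

#' Reference calibration of the prototype four-fibre sensor
#'
#' The decoding matrices obtained on the prototype sensor's physical
#' calibration rig (pitch/roll load sweep, 0-10 mN). These are the default
#' ground truth for the synthetic sweep generator, so that round trips
#' exercise realistic coefficient magnitudes. Note the rows of the
#' transverse matrix sum to zero, which makes the transverse decoding
#' exactly insensitive to common-mode shifts.
#'
#' @return An `fbg_calibration` object.
#' @export
reference_calibration <- function() {
  fbg_calibration(
    c_tran = matrix(c(-0.025, 0.111, -0.086,
                      -0.143, 0.274, -0.131), nrow = 2, byrow = TRUE),
    a_axi = c(-0.167, 0.109, -0.094, 0.382)
  )
}

#' Transverse force from common-mode-rejected shifts
#'
#' Matrix-vector product `c_tran %*% ds` assigning (F_X, F_Y).
#'
#' @param ds Numeric vector of 3 centred shifts (nm), or a matrix / data
#'   frame with 3 columns.
#' @param calib An [fbg_calibration()].
#' @return For a vector input, a named numeric `c(fx, fy)`; for tabular
#'   input, a tibble with columns `fx_mN`, `fy_mN`. Units mN.
#' @export
transverse_force <- function(ds, calib = reference_calibration()) {
  stopifnot(inherits(calib, "fbg_calibration"))
  if (is.data.frame(ds)) ds <- as.matrix(ds)
  if (is.matrix(ds)) {
    if (ncol(ds) != 3L) abort("`ds` must have 3 columns.")
    out <- ds %*% t(calib$c_tran)
    return(tibble(fx_mN = out[, 1], fy_mN = out[, 2]))
  }
  if (length(ds) != 3L) abort("`ds` must have 3 entries.")
  drop(calib$c_tran %*% ds) |> setNames(c("fx", "fy"))
}

#' Axial force from the four raw wavelength shifts
#'
#' Dot product of the axial decoding row with the shifts.
#'
#' @param shifts Numeric vector of 4 shifts (nm), or a matrix / data frame
#'   with 4 columns.
#' @inheritParams transverse_force
#' @return Axial force F_Z, mN (vector for tabular input).
#' @export
axial_force <- function(shifts, calib = reference_calibration()) {
  stopifnot(inherits(calib, "fbg_calibration"))
  if (is.data.frame(shifts)) shifts <- as.matrix(shifts)
  if (is.matrix(shifts)) {
    if (ncol(shifts) != 4L) abort("`shifts` must have 4 columns.")
    return(drop(shifts %*% calib$a_axi))
  }
  if (length(shifts) != 4L) abort("`shifts` must have 4 entries.")
  sum(calib$a_axi * shifts)
}

#' Compose a 3-D tip force with derived magnitudes
#'
#' Builds the full force record from the three Cartesian components:
#' the transverse magnitude `ft = sqrt(fx^2 + fy^2)` (the combined force of
#' F_X and F_Y) and the total magnitude `f_total = sqrt(fx^2 + fy^2 + fz^2)`.
#' Vectorised.
#'
#' @param fx,fy,fz Force components, mN.
#' @return A tibble with columns `fx_mN`, `fy_mN`, `fz_mN`, `ft_mN`,
#'   `f_total_mN`.
#' @examples
#' compose_force(3, 4, 0) # 3-4-5 triangle: ft = f_total = 5
#' @export
compose_force <- function(fx, fy, fz) {
  if (!all(is.finite(fx), is.finite(fy), is.finite(fz))) {
    abort("force components must be finite.")
  }
  tibble(
    fx_mN = fx, fy_mN = fy, fz_mN = fz,
    ft_mN = sqrt(fx^2 + fy^2),
    f_total_mN = sqrt(fx^2 + fy^2 + fz^2)
  )
}

# 3x4 operator that selects the calibration's fibre subset and centres it
# (common-mode rejection as a matrix)
subset_centering_matrix <- function(fiber_subset) {
  sel <- matrix(0, 3, 4)
  sel[cbind(1:3, fiber_subset)] <- 1
  (diag(3) - matrix(1 / 3, 3, 3)) %*% sel
}

# 3x4 decoder stacking transverse-on-centred-subset and axial rows:
# force = decoder %*% shifts
decoder_matrix <- function(calib) {
  rbind(calib$c_tran %*% subset_centering_matrix(calib$fiber_subset),
        calib$a_axi)
}

#' Force-to-shift forward matrix consistent with a calibration
#'
#' Returns the 4x3 matrix `G` (nm per mN) mapping a tip force
#' `(fx, fy, fz)` to the four noiseless wavelength shifts, constructed as
#' the minimum-norm right inverse of the calibration's stacked decoding
#' operator. Decoding shifts generated through `G` with the same
#' calibration returns the input force exactly; this is the forward model
#' used by the synthetic sweep generator.
#'
#' @inheritParams transverse_force
#' @return A 4x3 numeric matrix, nm/mN.
#' @export
forward_matrix <- function(calib = reference_calibration()) {
  stopifnot(inherits(calib, "fbg_calibration"))
  D <- decoder_matrix(calib)
  if (qr(D)$rank < 3L) {
    abort("calibration decoding operator is rank-deficient; no consistent forward model exists.")
  }
  t(D) %*% solve(D %*% t(D))
}

#' Physics-based force-to-shift forward matrix
#'
#' Alternative forward model built from first principles rather than from a
#' decoding matrix: fibre `i` (at 0, 90, 180, 270 degrees around the
#' needle, fibre 1 on +X) sees the bending strain of the transverse force
#' projected onto its plane, transduced through the needle's cantilever
#' compliance and the grating's strain coefficient, plus a shared axial
#' response to F_Z.
#'
#' @param geom A [needle_geometry()].
#' @param spec A [grating_spec()].
#' @param axial_gain Shared wavelength shift per unit axial force, nm/mN.
#' @return A 4x3 numeric matrix, nm/mN.
#' @export
physical_forward_matrix <- function(geom, spec = grating_spec(),
                                    axial_gain = 0.5) {
  stopifnot(inherits(geom, "needle_geometry"), inherits(spec, "grating_spec"))
  bend <- spec$strain_coeff * tip_strain(1, geom) # nm per mN of bending force
  phi <- deg2rad(fiber_angles_deg)
  cbind(bend * cos(phi), bend * sin(phi), rep(axial_gain, 4))
}

#' Simulate noiseless FBG readings for tip forces
#'
#' Runs the forward model: shifts `= G %*% force`, plus an optional common
#' temperature term on all four fibres.
#'
#' @param forces A data frame / tibble with columns `fx_mN`, `fy_mN`,
#'   `fz_mN` (extra columns are ignored), or a numeric matrix with 3
#'   columns.
#' @param forward Either an [fbg_calibration()] (its [forward_matrix()] is
#'   used) or a 4x3 forward matrix.
#' @param temp_change Temperature change, K (scalar or one per row).
#' @param spec A [grating_spec()] supplying the temperature coefficient;
#'   only used when `temp_change` is non-zero.
#' @return A tibble with columns `dlam1_nm` .. `dlam4_nm`.
#' @export
fbg_response <- function(forces, forward = reference_calibration(),
                         temp_change = 0, spec = grating_spec()) {
  G <- if (inherits(forward, "fbg_calibration")) forward_matrix(forward)
       else as.matrix(forward)
  if (!all(dim(G) == c(4L, 3L))) abort("`forward` must yield a 4x3 matrix.")
  if (is.data.frame(forces)) {
    forces <- as.matrix(forces[, c("fx_mN", "fy_mN", "fz_mN")])
  }
  if (ncol(forces) != 3L) abort("`forces` must have 3 columns.")
  shifts <- forces %*% t(G)
  if (any(temp_change != 0)) {
    shifts <- shifts + outer(rep(temp_change, length.out = nrow(shifts)),
                             rep(spec$temp_coeff, 4))
  }
  colnames(shifts) <- paste0("dlam", 1:4, "_nm")
  as_tibble(shifts)
}

#' Read or write a wavelength-shift log
#'
#' Plain CSV with columns `time_s`, `dlam1_nm` .. `dlam4_nm`.
#'
#' @param path File path.
#' @return `read_wavelength_log()` returns a tibble.
#' @export
read_wavelength_log <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("time_s", paste0("dlam", 1:4, "_nm"))
  if (!all(needed %in% names(out))) {
    abort(paste("wavelength log must have columns", toString(needed)))
  }
  out
}

#' @param log A tibble as returned by [read_wavelength_log()].
#' @rdname read_wavelength_log
#' @export
write_wavelength_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' Read or write a calibration model as JSON
#'
#' The JSON document carries `c_tran` (2x3 nested arrays), `a_axi`
#' (length-4 array), `fiber_subset` and a `units` string.
#'
#' @param path File path.
#' @return `read_calibration()` returns an [fbg_calibration()].
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  c_tran <- doc$c_tran
  if (!is.matrix(c_tran)) c_tran <- do.call(rbind, c_tran)
  fbg_calibration(
    c_tran = c_tran,
    a_axi = doc$a_axi,
    fiber_subset = doc$fiber_subset %||% 1:3
  )
}

#' @param calib An [fbg_calibration()].
#' @rdname read_calibration
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "fbg_calibration"))
  doc <- list(
    c_tran = lapply(seq_len(2), function(i) calib$c_tran[i, ]),
    a_axi = calib$a_axi,
    fiber_subset = calib$fiber_subset,
    units = "mN per nm"
  )
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.fbg_calibration <- function(x, ...) {
  cat("<fbg_calibration>  (mN per nm)\n")
  cat("transverse decoding (fibres", toString(x$fiber_subset),
      "after common-mode rejection):\n")
  print(round(x$c_tran, 4))
  cat("axial decoding (4 raw shifts):\n")
  print(round(x$a_axi, 4))
  if (!is.null(x$fit)) {
    cat("fitted on", x$fit$n, "samples; slopes:",
        toString(round(x$fit$slopes$slope, 4)), "\n")
  }
  invisible(x)
}
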