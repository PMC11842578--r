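#' Cell and channel parameters for holding mechanics
#'
#' Parameters of a spherical embryo resting in the microfluidic channel and
#' held at the suction port. Geometry is given in micrometres and densities
#' in g/cm^3 (converted to SI internally); defaults describe a zebrafish
#' embryo of radius 500 um and density 2.18 g/cm^3 in aqueous medium with a
#' 375 um holding port. The surface-tension coefficient and fluid-air
#' contact angle default to clean water against air (0.072 N/m, 0 degrees);
#' `contact_angle_deg` is the wetting angle in the holding-pressure
#' correction, not a calibration angle.
#'
#' @param cell_radius Embryo radius R, um.
#' @param cell_density Embryo density, g/cm^3.
#' @param fluid_density Medium density, g/cm^3.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param holding_radius Holding-channel radius R_H, um (must be < R).
#' @param surface_tension Surface-tension coefficient sigma, N/m.
#' @param contact_angle_deg Fluid-air contact angle, degrees, in \[0, 90).
#'
#' @return An object of class `cell_system_params`.
#' @export
cell_system_params <- function(cell_radius = 500, cell_density = 2.18,
                               fluid_density = 1.0, gravity = 10,
                               holding_radius = 375,
                               surface_tension = 0.072,
                               contact_angle_deg = 0) {
  stop_if_not_number(cell_radius, "cell_radius", positive = TRUE)
  stop_if_not_number(cell_density, "cell_density", positive = TRUE)
  stop_if_not_number(fluid_density, "fluid_density", positive = TRUE)
  stop_if_not_number(gravity, "gravity", positive = TRUE)
  stop_if_not_number(holding_radius, "holding_radius", positive = TRUE)
  stop_if_not_number(surface_tension, "surface_tension")
  stop_if_not_number(contact_angle_deg, "contact_angle_deg")
  if (holding_radius >= cell_radius) {
    abort("`holding_radius` must be smaller than `cell_radius`.")
  }
  if (contact_angle_deg < 0 || contact_angle_deg >= 90) {
    abort("`contact_angle_deg` must be in [0, 90).")
  }
  structure(
    list(cell_radius = cell_radius, cell_density = cell_density,
         fluid_density = fluid_density, gravity = gravity,
         holding_radius = holding_radius, surface_tension = surface_tension,
         contact_angle_deg = contact_angle_deg),
    class = "cell_system_params"
  )
}

# unit conversions: um -> m, g/cm^3 -> kg/m^3
um_to_m <- function(x) x * 1e-6
gcm3_to_kgm3 <- function(x) x * 1000

#' Net weight of the submerged cell
#'
#' Gravity minus buoyancy: `(4/3) pi R^3 (rho_c - rho_f) g`.
#'
#' @param params A [cell_system_params()].
#' @return Net weight, N.
#' @export
net_weight <- function(params) {
  stopifnot(inherits(params, "cell_system_params"))
  R <- um_to_m(params$cell_radius)
  drho <- gcm3_to_kgm3(params$cell_density - params$fluid_density)
  4 / 3 * pi * R^3 * drho * params$gravity
}

#' Contact geometry at the holding port
#'
#' The seated sphere touches the port rim on a circle of radius `R_H`; the
#' offset from the sphere centre to the rim plane is `L = sqrt(R^2 - R_H^2)`
#' and the seating angle is `theta = acos(R_H / R)`.
#'
#' @inheritParams net_weight
#' @return A list with `L_um` (offset, um) and `theta_deg` (degrees).
#' @examples
#' contact_geometry(cell_system_params()) # L = 330.72 um, theta = 41.41 deg
#' @export
contact_geometry <- function(params) {
  stopifnot(inherits(params, "cell_system_params"))
  R <- params$cell_radius
  RH <- params$holding_radius
  if (RH >= R) abort("holding radius must be smaller than the cell radius.")
  list(L_um = sqrt(R^2 - RH^2), theta_deg = rad2deg(acos(RH / R)))
}

#' Minimum drag force to mobilise the resting cell
#'
#' Static threshold from the inclined-support balance: with seating angle
#' `theta`, the support reaction is `net_weight / cos(theta)` and the drag
#' needed to unseat the cell is `net_weight * tan(theta)`.
#'
#' @inheritParams net_weight
#' @param theta_deg Optional override of the seating angle (degrees); by
#'   default taken from [contact_geometry()].
#' @return Minimum drag force, N.
#' @export
min_drag_force <- function(params, theta_deg = NULL) {
  stopifnot(inherits(params, "cell_system_params"))
  theta <- theta_deg %||% contact_geometry(params)$theta_deg
  if (theta >= 90) abort("seating angle of 90 degrees leaves the drag undefined.")
  net_weight(params) * tan(deg2rad(theta))
}

#' Critical holding pressure
#'
#' Minimum suction keeping the seated cell attached against the moment of
#' its net weight about the port rim:
#' `P_C = (4/3) (rho_c - rho_f) (R / R_H)^3 g L`, plus the surface-tension
#' correction `4 sigma cos(beta) / (2 R_H)` (zero when
#' `include_surface_tension = FALSE` or `sigma = 0`).
#'
#' @inheritParams net_weight
#' @param include_surface_tension Include the wetting term?
#' @return Critical pressure, Pa.
#' @export
critical_holding_pressure <- function(params, include_surface_tension = TRUE) {
  stopifnot(inherits(params, "cell_system_params"))
  drho <- gcm3_to_kgm3(params$cell_density - params$fluid_density)
  L <- um_to_m(contact_geometry(params)$L_um)
  RH <- um_to_m(params$holding_radius)
  ratio <- params$cell_radius / params$holding_radius
  p <- 4 / 3 * drho * ratio^3 * params$gravity * L
  if (include_surface_tension && params$surface_tension != 0) {
    p <- p + 4 * params$surface_tension *
      cos(deg2rad(params$contact_angle_deg)) / (2 * RH)
  }
  p
}

#' Moment terms about the holding-port rim
#'
#' The four moments entering the detachment balance, taken about the rim
#' point: buoyancy `M_FB = (4/3) pi R^3 rho_f g L`, gravity
#' `M_G = -(4/3) pi R^3 rho_c g L`, the contact reaction `M_FN = 0` (the
#' cell is about to detach), and the holding suction
#' `M_FH = pi R_H^3 P_C`. At the critical pressure (without surface
#' tension) the four terms sum to zero.
#'
#' @inheritParams net_weight
#' @param holding_pressure Applied holding pressure, Pa.
#' @return A tibble with columns `term` and `moment_Nm`.
#' @export
moment_terms <- function(params, holding_pressure) {
  stopifnot(inherits(params, "cell_system_params"))
  stop_if_not_number(holding_pressure, "holding_pressure")
  R <- um_to_m(params$cell_radius)
  RH <- um_to_m(params$holding_radius)
  L <- um_to_m(contact_geometry(params)$L_um)
  g <- params$gravity
  tibble(
    term = c("M_FB", "M_G", "M_FN", "M_FH"),
    moment_Nm = c(
      4 / 3 * pi * R^3 * gcm3_to_kgm3(params$fluid_density) * g * L,
      -4 / 3 * pi * R^3 * gcm3_to_kgm3(params$cell_density) * g * L,
      0,
      pi * RH^3 * holding_pressure
    )
  )
}

#' Full mechanics report for a cell/channel configuration
#'
#' Computes every quantity of the holding analysis in one pass and checks
#' the moment balance at the critical pressure.
#'
#' @inheritParams net_weight
#' @return An object of class `mechanics_report`: a list with
#'   `net_weight_N`, `contact_offset_um`, `contact_angle_theta_deg`,
#'   `min_drag_N`, `critical_pressure_Pa` (with surface tension),
#'   `critical_pressure_base_Pa` (without), `moments` (tibble at the base
#'   critical pressure) and `moment_balance_residual` (relative to the
#'   largest moment).
#' @export
mechanics_report <- function(params = cell_system_params()) {
  geo <- contact_geometry(params)
  p_base <- critical_holding_pressure(params, include_surface_tension = FALSE)
  moments <- moment_terms(params, p_base)
  res <- abs(sum(moments$moment_Nm)) / max(abs(moments$moment_Nm))
  structure(
    list(
      params = params,
      net_weight_N = net_weight(params),
      contact_offset_um = geo$L_um,
      contact_angle_theta_deg = geo$theta_deg,
      min_drag_N = min_drag_force(params),
      critical_pressure_Pa = critical_holding_pressure(params),
      critical_pressure_base_Pa = p_base,
      moments = moments,
      moment_balance_residual = res
    ),
    class = "mechanics_report"
  )
}

#' @export
print.mechanics_report <- function(x, ...) {
  cat("<mechanics_report>\n")
  cat(sprintf("  net weight            %.4g N\n", x$net_weight_N))
  cat(sprintf("  contact offset L      %.2f um\n", x$contact_offset_um))
  cat(sprintf("  seating angle theta   %.2f deg\n", x$contact_angle_theta_deg))
  cat(sprintf("  minimum drag          %.4g N\n", x$min_drag_N))
  cat(sprintf("  critical pressure     %.2f Pa  (%.2f Pa without surface tension)\n",
              x$critical_pressure_Pa, x$critical_pressure_base_Pa))
  cat(sprintf("  moment balance        |sum M| / max |M| = %.2e\n",
              x$moment_balance_residual))
  invisible(x)
}

#' @method tidy mechanics_report
#' @export
tidy.mechanics_report <- function(x, ...) {
  tibble(
    quantity = c("net_weight_N", "contact_offset_um",
                 "contact_angle_theta_deg", "min_drag_N",
                 "critical_pressure_Pa", "critical_pressure_base_Pa",
                 "moment_balance_residual"),
    value = c(x$net_weight_N, x$contact_offset_um, x$contact_angle_theta_deg,
              x$min_drag_N, x$critical_pressure_Pa,
              x$critical_pressure_base_Pa, x$moment_balance_residual)
  )
}
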