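#' Embolic particle specification
#'
#' A spherical embolus with diameter `phi` and density `rho_p`. Derived
#' quantities: cross-section `A = pi phi^2 / 4` and mass
#' `m = (pi/6) phi^3 rho_p`.
#'
#' @param diameter particle diameter in metres (e.g. `500e-6` for 500 microns).
#' @param density particle density in kg/m^3.
#' @param label optional case label (see [particle_case()]).
#' @return an object of class `particle_spec`.
#' @export
particle_spec <- function(diameter, density, label = NULL) {
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  if (!is.numeric(density) || density < 0) stop("density must be >= 0", call. = FALSE)
  structure(list(diameter = diameter, density = density,
                 area = pi * diameter^2 / 4,
                 mass = pi / 6 * diameter^3 * density,
                 label = label %||% sprintf("d%.0fum_rho%.0f", diameter * 1e6, density)),
            class = "particle_spec")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' The nine-case particle study matrix
#'
#' Diameters 200, 500 and 800 microns (case letters A--C) crossed with
#' densities 800, 1050 and 1300 kg/m^3 (case digits 1--3): lighter-than-blood
#' red emboli, near-neutral, and denser-than-blood white emboli.
#'
#' @return data frame with columns `case`, `diameter_um`, `density`, and the
#'   conventional per-case mass in mg as printed in study tables
#'   (see [table_mass()]).
#' @export
table2_cases <- function() {
  grid <- expand.grid(digit = 1:3, letter = c("A", "B", "C"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dia <- c(A = 200, B = 500, C = 800)[grid$letter]
  rho <- c(800, 1050, 1300)[grid$digit]
  data.frame(case = paste0(grid$letter, grid$digit),
             diameter_um = as.numeric(dia), density = rho,
             mass_mg = vapply(seq_len(nrow(grid)), function(i)
               table_mass(particle_spec(dia[i] * 1e-6, rho[i])), 0))
}

#' Particle spec for a named study case (A1 .. C3)
#' @param label case label; letter = diameter (A=200, B=500, C=800 microns),
#'   digit = density (1=800, 2=1050, 3=1300 kg/m^3).
#' @export
particle_case <- function(label) {
  tab <- table2_cases()
  row <- tab[tab$case == label, ]
  if (nrow(row) != 1L)
    stop("unknown case label '", label, "' (expected one of ",
         paste(tab$case, collapse = ", "), ")", call. = FALSE)
  particle_spec(row$diameter_um * 1e-6, row$density, label = label)
}

#' Particle mass (kg)
#' @param spec a [particle_spec()].
#' @export
particle_mass <- function(spec) pi / 6 * spec$diameter^3 * spec$density

#' Conventional tabulated particle mass (mg)
#'
#' The doubled-diameter convention `(pi/6) (2 phi)^3 rho`, expressed in mg
#' (equal to 8 times [particle_mass()], unit-converted). Provided solely for
#' regression against printed case tables that follow this convention; the
#' simulation itself always uses [particle_mass()].
#'
#' @param spec a [particle_spec()].
#' @export
table_mass <- function(spec) {
  pi / 6 * (2 * spec$diameter)^3 * spec$density * 1e6
}

#' Particle relaxation time (s)
#'
#' `tau_p = rho_p phi^2 / (18 mu)`, the Stokes time scale on which drag
#' equilibrates the particle with the surrounding fluid.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @export
relaxation_time <- function(spec, fluid = fluid_properties()) {
  spec$density * spec$diameter^2 / (18 * fluid$viscosity)
}

#' Particle relative (slip) Reynolds number
#'
#' `Re_s = rho_F |U_s| phi / mu_F` with `U_s` the slip velocity between the
#' particle and the blood.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param slip_speed |U_s| in m/s.
#' @export
slip_reynolds <- function(spec, fluid = fluid_properties(), slip_speed) {
  if (any(slip_speed < 0)) stop("slip speed must be >= 0", call. = FALSE)
  fluid$density * slip_speed * spec$diameter / fluid$viscosity
}

#' @noRd
drag_cap_value <- function(mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (mode == "standard") 0.44 else 44
}

#' Schiller--Naumann drag coefficient with inertial cap
#'
#' `C_D = max((24/Re)(1 + 0.15 Re^0.687), cap)`. The standard cap is 0.44
#' (Newton regime); `"literal"` uses 44 instead, retained as an alternative
#' convention.
#'
#' @param re_s slip Reynolds number (> 0).
#' @param mode `"standard"` (cap 0.44) or `"literal"` (cap 44).
#' @export
drag_coefficient <- function(re_s, mode = c("standard", "literal")) {
  if (any(re_s <= 0))
    stop("Re_s must be > 0; at zero slip use drag_force(), which is regular there",
         call. = FALSE)
  cap <- drag_cap_value(mode)
  pmax(24 / re_s * (1 + 0.15 * re_s^0.687), cap)
}

#' Drag force on the particle (N)
#'
#' `F_D = 0.5 C_D rho_F A_P |U_s| U_s` with `U_s = U_F - U_p`, so the force
#' drives the particle toward the fluid velocity. Below the cap this is
#' evaluated in the Stokes-factorized form
#' `3 pi mu phi (1 + 0.15 Re^0.687) U_s`, which is regular as `U_s -> 0`.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param u_fluid,u_particle velocity vectors in m/s.
#' @param mode drag cap mode, see [drag_coefficient()].
#' @return force vector in N.
#' @export
drag_force <- function(spec, fluid = fluid_properties(), u_fluid, u_particle,
                       mode = c("standard", "literal")) {
  us <- as.numeric(u_fluid) - as.numeric(u_particle)
  s <- vnorm(us)
  cap <- drag_cap_value(mode)
  re <- fluid$density * s * spec$diameter / fluid$viscosity
  beta_sn <- 3 * pi * fluid$viscosity * spec$diameter * (1 + 0.15 * re^0.687)
  beta_cap <- 0.5 * cap * fluid$density * spec$area * s
  max(beta_sn, beta_cap) * us
}

#' Buoyancy force (N)
#'
#' `F_B = (pi/6) phi^3 (rho_p - rho_F) g`: zero for a neutrally buoyant
#' particle, antiparallel to gravity when the particle is lighter than blood.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param gravity acceleration vector in m/s^2.
#' @export
buoyancy_force <- function(spec, fluid = fluid_properties(),
                           gravity = c(0, 0, -9.81)) {
  pi / 6 * spec$diameter^3 * (spec$density - fluid$density) * as.numeric(gravity)
}

#' Pressure-gradient force (N)
#'
#' `F_P = -(pi/6) phi^3 grad(p)`: the surrounding pressure field pushes the
#' particle from high toward low pressure, i.e. downstream in a resistive
#' tube flow.
#'
#' @param spec a [particle_spec()].
#' @param grad_p pressure-gradient vector in Pa/m.
#' @export
pressure_gradient_force <- function(spec, grad_p) {
  -pi / 6 * spec$diameter^3 * as.numeric(grad_p)
}

#' Virtual (added) mass (kg)
#'
#' `C_VM rho_F (pi/6) phi^3`: the fluid mass co-accelerated with the particle.
#' It augments the particle inertia on the left-hand side of the momentum
#' balance; the fluid-acceleration part of the virtual-mass force is evaluated
#' along the trajectory by finite differences of the sampled fluid velocity.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param c_vm virtual-mass coefficient (default 0.5 for a sphere).
#' @export
added_mass <- function(spec, fluid = fluid_properties(), c_vm = 0.5) {
  if (c_vm < 0) stop("c_vm must be >= 0", call. = FALSE)
  c_vm * fluid$density * pi / 6 * spec$diameter^3
}

#' Wall restitution coefficients
#'
#' @param e_perp,e_par perpendicular and parallel restitution coefficients in
#'   `[0, 1]`; `(1, 1)` is an ideal elastic bounce, `(0, 0)` deposits the
#'   particle on the wall.
#' @export
collision_coefficients <- function(e_perp = 1, e_par = 1) {
  for (e in c(e_perp, e_par))
    if (!is.numeric(e) || e < 0 || e > 1)
      stop("restitution coefficients must lie in [0, 1]", call. = FALSE)
  structure(list(e_perp = e_perp, e_par = e_par), class = "collision_coefficients")
}

#' Kinematic state of a tracked particle
#'
#' @param position_mm position in mm.
#' @param velocity velocity vector in m/s.
#' @param time time since release in s.
#' @param path_length_m cumulative path length in m.
#' @param bounces wall-collision count.
#' @param status one of `"active"`, `"exited"`, `"trapped"`, `"deposited"`.
#' @param outlet outlet node id when `status == "exited"`.
#' @export
particle_state <- function(position_mm, velocity = c(0, 0, 0), time = 0,
                           path_length_m = 0, bounces = 0L, status = "active",
                           outlet = NULL) {
  status <- match.arg(status, c("active", "exited", "trapped", "deposited"))
  if (status == "exited" && is.null(outlet))
    stop("an exited state must carry its outlet id", call. = FALSE)
  structure(list(position_mm = as_point3(position_mm),
                 velocity = as_point3(velocity), time = time,
                 path_length_m = path_length_m, bounces = as.integer(bounces),
                 status = status, outlet = outlet),
            class = "particle_state")
}

#' Reflect a particle off a wall
#'
#' The velocity component normal to the wall is reversed and scaled by
#' `e_perp`, the tangential component scaled by `e_par`; the bounce counter is
#' incremented. With both coefficients zero the particle is deposited.
#'
#' @param state a [particle_state()] (must be active).
#' @param normal outward unit wall normal.
#' @param coeffs a [collision_coefficients()].
#' @return the post-collision [particle_state()].
#' @export
reflect <- function(state, normal, coeffs = collision_coefficients()) {
  if (state$status != "active")
    stop("can only reflect an active particle", call. = FALSE)
  normal <- as_point3(normal)
  if (abs(vnorm(normal) - 1) > 1e-8)
    stop("wall normal must be a unit vector", call. = FALSE)
  v <- state$velocity
  vn <- sum(v * normal)
  vt <- v - vn * normal
  state$velocity <- coeffs$e_par * vt - coeffs$e_perp * vn * normal
  state$bounces <- state$bounces + 1L
  if (coeffs$e_perp == 0 && coeffs$e_par == 0) {
    state$velocity <- c(0, 0, 0)
    state$status <- "deposited"
  }
  state
}
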