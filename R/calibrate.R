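#' Calibrate terminal radii to a territory outflow split
#'
#' Iteratively rescales the radii of the terminal (outlet) segments -- never
#' the trunk vessels -- until the solved territory outflow fractions match the
#' requested targets. Each iteration solves the resistance network, compares
#' achieved to target fractions per territory group, and scales every terminal
#' radius of the group by `(target/achieved)^(1/4)` (terminal resistance
#' varies as `r^-4`), clamped per iteration for stability. Within a territory
#' the relative outlet split set by the geometry is preserved.
#'
#' @param net a [vascular_network()].
#' @param fluid a [fluid_properties()].
#' @param bc a [boundary_spec()]; defaults to 0.2 m/s inlets, 0 Pa outlets.
#' @param target_fractions named percentages summing to 100. Names may be
#'   `MCA` (both sides combined), `MCA_R`, `MCA_L`, `ACA`, `POSTERIOR`.
#' @param tol convergence tolerance in percentage points (default 1).
#' @param max_iter maximum fixed-point iterations.
#' @return list with `network` (adjusted), `achieved` (named percentages),
#'   `iterations`, and `solution` (the final [flow_solution][solve_flow()]).
#' @export
calibrate_terminals <- function(net, fluid = fluid_properties(),
                                bc = boundary_spec(net),
                                target_fractions = c(ACA = 20, MCA = 60, POSTERIOR = 20),
                                tol = 1, max_iter = 50L) {
  if (abs(sum(target_fractions) - 100) > 1e-6)
    stop("target fractions must sum to 100", call. = FALSE)
  groups <- lapply(names(target_fractions), function(g) {
    terrs <- if (g == "MCA") c("MCA_R", "MCA_L") else g
    if (!all(terrs %in% TERRITORIES))
      stop("unknown territory in targets: ", g, call. = FALSE)
    segs <- names(Filter(function(s) s$role == "terminal" && s$territory %in% terrs,
                         net$segments))
    if (!length(segs))
      stop("territory '", g, "' has no terminal segments to calibrate", call. = FALSE)
    list(name = g, territories = terrs, segments = segs)
  })
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    sol <- solve_flow(net, fluid, bc)
    fr <- outlet_fractions(net, sol)
    achieved <- vapply(groups, function(g) sum(fr$territory[g$territories]), 0)
    names(achieved) <- vapply(groups, `[[`, "", "name")
    err <- max(abs(achieved - target_fractions[names(achieved)]))
    if (err <= tol)
      return(list(network = net, achieved = achieved, iterations = it,
                  solution = sol))
    for (g in groups) {
      f <- (target_fractions[[g$name]] / achieved[[g$name]])^(1 / 4)
      f <- min(max(f, 0.6), 1.6)
      for (sid in g$segments) {
        r <- net$segments[[sid]]$radius_mm * f
        net$segments[[sid]]$radius_mm <- min(max(r, 0.2), 2.5)
      }
    }
  }
  stop(structure(class = c("embotrack_calibration_error", "error", "condition"),
                 list(message = paste0(
                        "terminal calibration did not converge after ", max_iter,
                        " iterations; last achieved fractions: ",
                        paste(names(achieved), round(achieved, 2),
                              sep = "=", collapse = ", ")),
                      call = NULL, achieved = achieved)))
}

#' Fixed-mass-flow boundary conditions derived from a pressure solve
#'
#' Builds the fixed-flow ("M1") boundary specification: every outlet except a
#' single pressure-reference outlet receives a prescribed volumetric outflow.
#' Prescriptions are the territory target shares of the total inflow,
#' distributed within each territory proportionally to the per-outlet split of
#' a reference pressure-mode solve.
#'
#' @param net a [vascular_network()].
#' @param fluid a [fluid_properties()].
#' @param base_bc the pressure-mode [boundary_spec()] supplying inlet
#'   velocities and the reference solve.
#' @param territory_targets named percentages (`ACA`, `MCA`, `POSTERIOR`)
#'   summing to 100.
#' @param reference outlet node id kept at fixed pressure (default the first
#'   left-MCA outlet).
#' @return a fixed-flow [boundary_spec()].
#' @export
m1_boundary <- function(net, fluid = fluid_properties(),
                        base_bc = boundary_spec(net),
                        territory_targets = c(ACA = 20, MCA = 60, POSTERIOR = 20),
                        reference = "L_MCA_O1") {
  sol <- solve_flow(net, fluid, base_bc)
  fr <- outlet_fractions(net, sol)
  outlets <- nodes_of_kind(net, "outlet")
  terr_of <- vapply(setNames(outlets, outlets), function(nid) {
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    seg$territory
  }, "")
  group_of <- setNames(ifelse(terr_of %in% c("MCA_R", "MCA_L"), "MCA",
                              ifelse(terr_of == "POSTERIOR", "POSTERIOR", "ACA")),
                       names(terr_of))
  qtot <- sol$total_inflow
  target_pct <- setNames(numeric(length(outlets)), outlets)
  for (g in names(territory_targets)) {
    in_g <- names(group_of)[group_of == g]
    share <- fr$outlet[in_g] / sum(fr$outlet[in_g])
    target_pct[in_g] <- territory_targets[[g]] * share
  }
  fixed <- qtot * target_pct / 100
  fixed <- fixed[setdiff(outlets, reference)]
  boundary_spec(net, inlet_velocity = base_bc$inlet_velocities,
                outlet_pressure = base_bc$outlet_pressures,
                fixed_outlet_flows = fixed, pressure_reference = reference)
}

#' Build the default calibrated network and its flow solution
#'
#' Generates the requested circle-of-Willis variant, prolongs the inlets by
#' ten local diameters, calibrates the terminal radii to the physiological
#' ACA:MCA:posterior = 20:60:20 split, and solves the flow.
#'
#' @param variant a variant name or [cow_variant_spec()].
#' @param fluid a [fluid_properties()].
#' @param inlet_velocity m/s, applied to all inlets.
#' @param inlet_extension multiple of the local diameter for [extend_inlets()].
#' @param target_fractions,tol passed to [calibrate_terminals()].
#' @return list with `network`, `solution`, `fractions` (per territory) and
#'   `bc`.
#' @export
build_default_network <- function(variant = "complete",
                                  fluid = fluid_properties(),
                                  inlet_velocity = 0.2,
                                  inlet_extension = 10,
                                  target_fractions = c(ACA = 20, MCA = 60, POSTERIOR = 20),
                                  tol = 1) {
  net <- generate_cow(if (is.character(variant)) cow_variant_spec(variant) else variant)
  net <- extend_inlets(net, inlet_extension)
  bc <- boundary_spec(net, inlet_velocity = inlet_velocity)
  cal <- calibrate_terminals(net, fluid, bc, target_fractions, tol = tol)
  fr <- outlet_fractions(cal$network, cal$solution)
  list(network = cal$network, solution = cal$solution,
       fractions = fr$territory, bc = bc)
}
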