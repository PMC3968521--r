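#' Blood (carrier fluid) properties
#'
#' Defaults are whole blood treated as an incompressible Newtonian fluid:
#' density 1056 kg/m^3, dynamic viscosity 3.2e-3 Pa s.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @export
fluid_properties <- function(density = 1056, viscosity = 3.2e-3) {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0", call. = FALSE)
  if (!is.numeric(viscosity) || viscosity <= 0) stop("viscosity must be > 0", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions for the resistance-network solve
#'
#' The standard mode imposes a normal velocity on every inlet (converted to a
#' volumetric inflow through the inlet cross-section) and a constant pressure
#' (default 0 Pa) on every outlet plane. The fixed-flow mode ("M1") instead
#' prescribes the volumetric outflow of every outlet except one, which is kept
#' as the pressure reference so the system is not over-determined.
#'
#' @param net a [vascular_network()].
#' @param inlet_velocity scalar or named vector (m/s), one value per inlet
#'   node; default 0.2 m/s everywhere.
#' @param outlet_pressure scalar or named vector (Pa) for outlet planes.
#' @param fixed_outlet_flows optional named vector (m^3/s) of prescribed
#'   outflows; must cover every outlet except the `pressure_reference`.
#' @param pressure_reference outlet node id kept at fixed pressure in
#'   fixed-flow mode.
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(net, inlet_velocity = 0.2, outlet_pressure = 0,
                          fixed_outlet_flows = NULL, pressure_reference = NULL) {
  inlets <- nodes_of_kind(net, "inlet")
  outlets <- nodes_of_kind(net, "outlet")
  iv <- expand_named(inlet_velocity, inlets, "inlet_velocity")
  op <- expand_named(outlet_pressure, outlets, "outlet_pressure")
  mode <- "pressure"
  if (!is.null(fixed_outlet_flows)) {
    mode <- "fixed_flow"
    if (is.null(pressure_reference) || length(pressure_reference) != 1L)
      stop("fixed-flow mode needs exactly one pressure_reference outlet", call. = FALSE)
    if (!pressure_reference %in% outlets)
      stop("pressure_reference '", pressure_reference, "' is not an outlet", call. = FALSE)
    need <- setdiff(outlets, pressure_reference)
    if (!setequal(names(fixed_outlet_flows), need))
      stop("fixed_outlet_flows must cover every outlet except the pressure ",
           "reference; mismatch on: ",
           paste(union(setdiff(need, names(fixed_outlet_flows)),
                       setdiff(names(fixed_outlet_flows), need)), collapse = ", "),
           call. = FALSE)
  }
  structure(list(mode = mode, inlet_velocities = iv, outlet_pressures = op,
                 fixed_outlet_flows = fixed_outlet_flows,
                 pressure_reference = pressure_reference),
            class = "boundary_spec")
}

#' @noRd
expand_named <- function(x, ids, what) {
  if (length(x) == 1L && is.null(names(x))) return(setNames(rep(as.numeric(x), length(ids)), ids))
  if (!setequal(names(x), ids))
    stop(what, " must name every relevant node exactly once", call. = FALSE)
  setNames(as.numeric(x[ids]), ids)
}

#' Hagen--Poiseuille resistance of a vessel segment
#'
#' `8 mu L / (pi r^4)` with `L` the centerline polyline length.
#'
#' @param seg a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return resistance in Pa s/m^3.
#' @export
segment_resistance <- function(seg, fluid = fluid_properties()) {
  len <- segment_length(seg) * MM
  if (len <= 0) stop("segment '", seg$id, "' has zero length", call. = FALSE)
  r <- seg$radius_mm * MM
  8 * fluid$viscosity * len / (pi * r^4)
}

#' Solve steady flow on the network
#'
#' Assembles nodal flow conservation with Hagen--Poiseuille segment
#' conductances and solves for nodal pressures. Inlet velocity boundary
#' conditions are converted to fixed volumetric inflows `Q = v pi r^2`; in
#' fixed-flow mode the prescribed outlet flows enter as sinks and the single
#' pressure-reference outlet closes the system.
#'
#' @param net a [vascular_network()].
#' @param fluid a [fluid_properties()].
#' @param bc a [boundary_spec()].
#' @return an object of class `flow_solution` with `node_pressure` (Pa),
#'   `segment_flow` (m^3/s, signed positive proximal to distal) and
#'   `segment_mean_velocity` (m/s).
#' @export
solve_flow <- function(net, fluid = fluid_properties(), bc = boundary_spec(net)) {
  nodes <- names(net$nodes)
  nn <- length(nodes)
  idx <- setNames(seq_len(nn), nodes)
  segs <- net$segments
  g <- vapply(segs, function(s) 1 / segment_resistance(s, fluid), 0)

  A <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  b <- setNames(numeric(nn), nodes)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    i <- idx[[s$proximal]]; j <- idx[[s$distal]]
    A[i, i] <- A[i, i] + g[k]; A[j, j] <- A[j, j] + g[k]
    A[i, j] <- A[i, j] - g[k]; A[j, i] <- A[j, i] - g[k]
  }
  # inflow sources from inlet velocities
  inflow <- inlet_flows(net, bc)
  b[names(inflow)] <- b[names(inflow)] + inflow
  # Dirichlet pressures / fixed outlet flows
  if (bc$mode == "pressure") {
    dirichlet <- bc$outlet_pressures
  } else {
    dirichlet <- bc$outlet_pressures[bc$pressure_reference]
    fq <- bc$fixed_outlet_flows
    b[names(fq)] <- b[names(fq)] - fq
  }
  for (nm in names(dirichlet)) {
    i <- idx[[nm]]
    A[i, ] <- 0; A[i, i] <- 1; b[i] <- dirichlet[[nm]]
  }
  p <- tryCatch(solve(A, b), error = function(e) {
    comp <- igraph::components(network_graph(net))
    if (comp$no > 1L) {
      isl <- split(names(comp$membership), comp$membership)
      stop("flow system is singular: network has disconnected islands: ",
           paste(vapply(isl[-1], function(x) paste(x, collapse = "+"), ""),
                 collapse = "; "), call. = FALSE)
    }
    stop("flow system is singular: ", conditionMessage(e), call. = FALSE)
  })
  p <- setNames(as.numeric(p), nodes)
  q <- vapply(seq_along(segs), function(k) {
    s <- segs[[k]]; g[k] * (p[[s$proximal]] - p[[s$distal]])
  }, 0)
  names(q) <- names(segs)
  area <- vapply(segs, function(s) pi * (s$radius_mm * MM)^2, 0)
  sol <- structure(list(node_pressure = p, segment_flow = q,
                        segment_mean_velocity = q / area,
                        total_inflow = sum(inflow), bc_mode = bc$mode),
                   class = "flow_solution")
  imb <- max_junction_imbalance(net, sol)
  if (imb > 1e-8)
    warning("junction flow imbalance ", signif(imb, 3), " relative to inflow")
  sol
}

#' @noRd
inlet_flows <- function(net, bc) {
  inlets <- nodes_of_kind(net, "inlet")
  vapply(setNames(inlets, inlets), function(nid) {
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    bc$inlet_velocities[[nid]] * pi * (seg$radius_mm * MM)^2
  }, 0)
}

#' Maximum junction flow imbalance relative to total inflow
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @export
max_junction_imbalance <- function(net, sol) {
  jn <- nodes_of_kind(net, "junction")
  net_in <- setNames(numeric(length(jn)), jn)
  for (s in net$segments) {
    if (s$distal %in% jn) net_in[s$distal] <- net_in[s$distal] + sol$segment_flow[[s$id]]
    if (s$proximal %in% jn) net_in[s$proximal] <- net_in[s$proximal] - sol$segment_flow[[s$id]]
  }
  if (!length(jn)) return(0)
  max(abs(net_in)) / sol$total_inflow
}

#' Outflow fractions per outlet and per territory
#'
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @return list with `outlet` (named percentages of total inflow) and
#'   `territory` (aggregates over MCA_R, MCA_L, ACA, POSTERIOR).
#' @export
outlet_fractions <- function(net, sol) {
  if (!inherits(sol, "flow_solution")) stop("sol must be a flow_solution", call. = FALSE)
  outlets <- nodes_of_kind(net, "outlet")
  q_out <- vapply(setNames(outlets, outlets), function(nid) {
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    if (seg$distal == nid) sol$segment_flow[[seg$id]] else -sol$segment_flow[[seg$id]]
  }, 0)
  pct <- 100 * q_out / sol$total_inflow
  terr_of <- vapply(setNames(outlets, outlets), function(nid) {
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    seg$territory
  }, "")
  terr <- vapply(c(MCA_R = "MCA_R", MCA_L = "MCA_L", ACA = "ACA",
                   POSTERIOR = "POSTERIOR"),
                 function(tt) sum(pct[terr_of == tt]), 0)
  list(outlet = pct, territory = terr)
}

#' Local fluid velocity inside the lumen
#'
#' Inside a single tube the axial Poiseuille profile
#' `u = 2 (Q/pi r^2) (1 - (s/r)^2)` is returned along the local tangent,
#' oriented by the sign of the solved flow; the no-slip wall gives zero
#' velocity at `s = r`. In junction overlap regions the profiles of all
#' containing tubes are blended with inverse-distance-to-axis weights.
#'
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @param p query point in mm.
#' @return velocity vector in m/s.
#' @export
velocity_at <- function(net, sol, p) {
  field_at(net, sol, p)$velocity
}

#' Local pressure gradient inside the lumen
#'
#' Uniform within a segment, magnitude `dP/L`, directed so that pressure
#' decreases along the local flow direction; blended across junction overlaps
#' like [velocity_at()].
#'
#' @inheritParams velocity_at
#' @return pressure-gradient vector in Pa/m.
#' @export
pressure_gradient_at <- function(net, sol, p) {
  field_at(net, sol, p)$pressure_gradient
}

#' @noRd
field_at <- function(net, sol, p) {
  p <- as_point3(p)
  fl <- flatten_network(net, sol)
  res <- cpp_field_eval(fl$pts, fl$seg_ptr, fl$radius, fl$mean_vel, fl$dpds,
                        fl$terminal, fl$jn_pos, fl$jn_R, fl$port_ptr, fl$port_pos, fl$port_q, fl$port_dir,
                        matrix(p * MM, nrow = 1))
  if (res$inside[1] == 0L)
    stop("point is outside the lumen", call. = FALSE)
  list(velocity = as.numeric(res$velocity[1, ]),
       pressure_gradient = as.numeric(res$gradp[1, ]))
}

#' Distance to the nearest vessel wall
#'
#' @param net a [vascular_network()].
#' @param p point in mm (must be inside the lumen).
#' @return list with `distance_mm` and the outward unit `normal`.
#' @export
wall_distance <- function(net, p) {
  p <- as_point3(p)
  fl <- flatten_network(net)
  res <- cpp_locate(fl$pts, fl$seg_ptr, fl$radius, matrix(p * MM, nrow = 1))
  if (res$inside[1] == 0L)
    stop("point is outside the lumen", call. = FALSE)
  list(distance_mm = res$wall_dist[1] / MM,
       normal = as.numeric(res$normal[1, ]))
}

#' Export a flow solution to CSV
#'
#' Writes one table of per-segment flows and mean velocities, and one of
#' per-outlet outflow percentages (outlet label, percent).
#'
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @param segments_csv,fractions_csv output paths (either may be `NULL`).
#' @return invisibly, the list of written data frames.
#' @export
export_flow_csv <- function(net, sol, segments_csv = NULL, fractions_csv = NULL) {
  seg_df <- data.frame(segment = names(net$segments),
                       flow_m3_s = as.numeric(sol$segment_flow),
                       mean_velocity_m_s = as.numeric(sol$segment_mean_velocity))
  fr <- outlet_fractions(net, sol)
  fr_df <- data.frame(outlet = names(fr$outlet), percent = as.numeric(fr$outlet))
  if (!is.null(segments_csv)) write.csv(seg_df, segments_csv, row.names = FALSE)
  if (!is.null(fractions_csv)) write.csv(fr_df, fractions_csv, row.names = FALSE)
  invisible(list(segments = seg_df, fractions = fr_df))
}
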