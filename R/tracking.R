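#' Advance one particle by a single outer time step
#'
#' Integrates the momentum balance (drag, buoyancy, pressure-gradient and
#' virtual-mass forces) over one outer step `config$dt` using drag-implicit
#' (exponential) substeps, handling wall bounces and outlet crossings.
#'
#' @param state a [particle_state()] (must be active).
#' @param spec a [particle_spec()].
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @param fluid a [fluid_properties()].
#' @param config a [sim_config()].
#' @return the updated [particle_state()].
#' @export
step_particle <- function(state, spec, net, sol, fluid = fluid_properties(),
                 config = sim_config()) {
  if (state$status != "active") stop("particle is not active", call. = FALSE)
  fl <- flatten_network(net, sol)
  res <- cpp_track_particle(
    fl$pts, fl$seg_ptr, fl$radius, fl$mean_vel, fl$dpds, fl$terminal,
    fl$jn_pos, fl$jn_R, fl$port_ptr, fl$port_pos, fl$port_q, fl$port_dir,
    state$position_mm * MM, state$velocity, state$time,
    state$time + config$dt, config$dt,
    spec$diameter, spec$density, fluid$density, fluid$viscosity,
    config$gravity, config$c_vm, drag_cap_value(config$drag_cap),
    config$e_perp, config$e_par, config$substep_factor)
  if (res$status == 4L)
    stop("particle integration diverged (non-finite state) at t=",
         signif(res$t_end, 4), " s near position (",
         paste(signif(res$x_end / MM, 4), collapse = ", "), ") mm", call. = FALSE)
  status <- c("active", "exited", "deposited", "trapped")[res$status + 1L]
  if (status == "trapped") status <- "active"  # single step: caller owns the clock
  outlet <- NULL
  if (status == "exited")
    outlet <- net$segments[[fl$seg_ids[res$exit_seg]]]$distal
  particle_state(position_mm = res$x_end / MM, velocity = res$v_end,
                 time = res$t_end,
                 path_length_m = state$path_length_m + res$path,
                 bounces = state$bounces + res$bounces,
                 status = status, outlet = outlet)
}

#' Track every particle of a release schedule through the network
#'
#' Runs the full two-phase simulation: particles are injected according to the
#' protocol during the release window and tracked until they exit through an
#' outlet plane, deposit on a wall (only possible with zero restitution), or
#' the total simulation time elapses (trapped). Trajectories are sampled at
#' every outer step.
#'
#' @param net a [vascular_network()].
#' @param sol a [flow_solution][solve_flow()].
#' @param spec a [particle_spec()].
#' @param protocol a [release_protocol()].
#' @param config a [sim_config()].
#' @param fluid a [fluid_properties()].
#' @return a `trajectory_set`: list of `trajectory_record` objects with fields
#'   `particle_id`, `case`, `release_inlet`, `release_mode`, `release_time`,
#'   `times`, `positions_mm`, `speeds`, `status`, `outlet`, `path_m`,
#'   `residence_s`, `bounces`.
#' @export
run_particles <- function(net, sol, spec, protocol = release_protocol("core"),
                          config = sim_config(), fluid = fluid_properties()) {
  sched <- make_release_schedule(protocol, net, config)
  fl <- flatten_network(net, sol)
  cap <- drag_cap_value(config$drag_cap)
  records <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    row <- sched[i, ]
    res <- cpp_track_particle(
      fl$pts, fl$seg_ptr, fl$radius, fl$mean_vel, fl$dpds, fl$terminal,
      fl$jn_pos, fl$jn_R, fl$port_ptr, fl$port_pos, fl$port_q, fl$port_dir,
      c(row$x_mm, row$y_mm, row$z_mm) * MM, c(row$vx, row$vy, row$vz),
      row$time, config$t_total, config$dt,
      spec$diameter, spec$density, fluid$density, fluid$viscosity,
      config$gravity, config$c_vm, cap,
      config$e_perp, config$e_par, config$substep_factor)
    if (res$status == 4L)
      stop("particle ", row$particle_id, " diverged (non-finite state) at t=",
           signif(res$t_end, 4), " s", call. = FALSE)
    status <- c("active", "exited", "deposited", "trapped")[res$status + 1L]
    if (status == "active") status <- "trapped"
    outlet <- NA_character_
    if (status == "exited")
      outlet <- net$segments[[fl$seg_ids[res$exit_seg]]]$distal
    records[[i]] <- structure(list(
      particle_id = row$particle_id, case = spec$label,
      release_inlet = row$inlet, release_mode = attr(sched, "mode"),
      release_time = row$time,
      times = res$times, positions_mm = res$pos / MM, speeds = res$speed,
      status = status, outlet = outlet, path_m = res$path,
      residence_s = res$t_end - row$time, bounces = res$bounces),
      class = "trajectory_record")
  }
  structure(records, class = "trajectory_set",
            case = spec$label, mode = attr(sched, "mode"))
}

#' Integrate a particle in an unbounded uniform fluid
#'
#' Free-field version of the tracker (no walls, uniform fluid velocity, zero
#' pressure gradient), used to verify terminal settling velocities against the
#' drag--buoyancy balance.
#'
#' @param spec a [particle_spec()].
#' @param fluid a [fluid_properties()].
#' @param config a [sim_config()] (supplies gravity, drag cap, substeps).
#' @param u_fluid uniform fluid velocity (m/s).
#' @param v0 initial particle velocity (m/s).
#' @param duration simulated time in s.
#' @return list with `velocity` (final, m/s), `position_m` and `times`/`speeds`
#'   sampled at the outer step.
#' @export
track_free <- function(spec, fluid = fluid_properties(), config = sim_config(),
                       u_fluid = c(0, 0, 0), v0 = c(0, 0, 0), duration = 1) {
  res <- cpp_track_free(
    spec$diameter, spec$density, fluid$density, fluid$viscosity,
    config$gravity, config$c_vm, drag_cap_value(config$drag_cap),
    as_point3(u_fluid), as_point3(v0), duration, config$dt,
    config$substep_factor)
  list(velocity = res$v_end, position_m = res$x_end,
       times = res$times, speeds = res$speed)
}

#' Summarise a set of trajectory records
#'
#' @param records a `trajectory_set` (or plain list of `trajectory_record`s).
#' @return data frame with one row per particle: id, case, release inlet and
#'   mode, outcome, outlet, residence time (s), path length (mm), bounce count
#'   and average travel speed (m/s; `NA` for non-exited particles).
#' @export
summarize_records <- function(records) {
  do.call(rbind, lapply(records, function(r) data.frame(
    particle_id = r$particle_id, case = r$case %||% NA_character_,
    release_inlet = r$release_inlet, release_mode = r$release_mode,
    release_time = r$release_time, status = r$status,
    outlet = r$outlet %||% NA_character_,
    residence_s = r$residence_s, path_mm = r$path_m / MM,
    bounces = r$bounces,
    avg_speed_m_s = if (r$status == "exited") r$path_m / r$residence_s else NA_real_,
    stringsAsFactors = FALSE)))
}

#' @export
print.trajectory_set <- function(x, ...) {
  st <- table(vapply(x, `[[`, "", "status"))
  cat("<trajectory_set> case ", attr(x, "case") %||% "?", ", ",
      attr(x, "mode") %||% "?", " release: ", length(x), " particles (",
      paste(names(st), st, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Export trajectories to CSV
#'
#' One row per sampled point: `particle_id, case, release_inlet, t_s, x_mm,
#' y_mm, z_mm, speed_m_s, status`.
#'
#' @param records a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectories_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) data.frame(
    particle_id = r$particle_id, case = r$case %||% NA_character_,
    release_inlet = r$release_inlet, t_s = r$times,
    x_mm = r$positions_mm[, 1], y_mm = r$positions_mm[, 2],
    z_mm = r$positions_mm[, 3], speed_m_s = r$speeds, status = r$status,
    stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
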