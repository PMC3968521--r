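#' Simulation configuration
#'
#' @param dt outer time step in s (default 0.01); trajectories are sampled at
#'   this cadence and releases are scheduled on it.
#' @param t_total total simulated time in s (default 5).
#' @param gravity acceleration vector in m/s^2; default `(0, 0, -9.81)` with
#'   +z the superior axis. Set to `c(0,0,0)` to disable.
#' @param drag_cap drag-coefficient cap mode, see [drag_coefficient()].
#' @param c_vm virtual-mass coefficient (default 0.5).
#' @param substep_factor fraction of the particle relaxation time used as the
#'   drag-resolving substep (default 0.1). Because drag is integrated exactly
#'   (exponential integrator) the substep is floored at `dt/100`; accuracy is
#'   then governed by field variation along the path, which the displacement
#'   guard (at most half a local radius per substep) controls.
#' @param e_perp,e_par wall restitution coefficients (default 1, 1: elastic).
#' @param seed integer seed for the release-position jitter.
#' @export
sim_config <- function(dt = 0.01, t_total = 5, gravity = c(0, 0, -9.81),
                       drag_cap = c("standard", "literal"), c_vm = 0.5,
                       substep_factor = 0.1, e_perp = 1, e_par = 1, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_total < dt) stop("t_total must be >= dt", call. = FALSE)
  drag_cap <- match.arg(drag_cap)
  collision_coefficients(e_perp, e_par)  # range check
  structure(list(dt = dt, t_total = t_total, gravity = as_point3(gravity),
                 drag_cap = drag_cap, c_vm = c_vm,
                 substep_factor = substep_factor,
                 e_perp = e_perp, e_par = e_par, seed = as.integer(seed)),
            class = "sim_config")
}

#' Particle release protocol
#'
#' Two canonical protocols: `"core"` releases one particle per inlet per outer
#' time step at the inlet-plane centre (3 per step on the default network);
#' `"near_wall"` releases six per step at radial fraction 0.9 of the inlet
#' radius -- three sites in the left ICA, two in the right ICA, one in the
#' basilar artery. Releases continue for `window_steps` outer steps and then
#' stop (two-phase protocol: injection, then tracking only).
#'
#' @param mode `"core"` or `"near_wall"`.
#' @param sites optional data frame overriding the default sites, with columns
#'   `inlet` (inlet node id), `radial_fraction` (in `[0, 1)`) and `angle`
#'   (radians, in the inlet plane).
#' @param particles_per_site_per_step released per site per outer step.
#' @param injection_speed m/s, directed into the vessel along the inlet
#'   tangent (default 0.2, matching the inflow).
#' @param jitter_sd seeded Gaussian jitter of the release position, as a
#'   fraction of the inlet radius (default 0.05).
#' @param window_steps number of outer steps in the release window.
#' @export
release_protocol <- function(mode = c("core", "near_wall"), sites = NULL,
                             particles_per_site_per_step = 1L,
                             injection_speed = 0.2, jitter_sd = 0.05,
                             window_steps = 100L) {
  mode <- match.arg(mode)
  if (!is.null(sites)) {
    need <- c("inlet", "radial_fraction", "angle")
    if (!all(need %in% names(sites)))
      stop("custom sites need columns: ", paste(need, collapse = ", "), call. = FALSE)
    if (any(sites$radial_fraction < 0 | sites$radial_fraction >= 1))
      stop("radial_fraction must lie in [0, 1)", call. = FALSE)
    if (!nrow(sites)) stop("sites must be non-empty", call. = FALSE)
  }
  structure(list(mode = mode, sites = sites,
                 particles_per_site_per_step = as.integer(particles_per_site_per_step),
                 injection_speed = injection_speed, jitter_sd = jitter_sd,
                 window_steps = as.integer(window_steps)),
            class = "release_protocol")
}

#' @noRd
default_sites <- function(mode, net) {
  inlets <- nodes_of_kind(net, "inlet")
  if (mode == "core") {
    data.frame(inlet = inlets, radial_fraction = 0, angle = 0,
               stringsAsFactors = FALSE)
  } else {
    # near-wall: 3 sites in L_ICA, 2 in R_ICA, 1 in BA (evenly spaced angles);
    # on non-default networks fall back to one site per inlet
    counts <- c(L_ICA_in = 3L, R_ICA_in = 2L, BA_in = 1L)
    if (!all(names(counts) %in% inlets))
      counts <- setNames(rep(1L, length(inlets)), inlets)
    do.call(rbind, lapply(names(counts), function(nid) {
      k <- counts[[nid]]
      data.frame(inlet = nid, radial_fraction = 0.9,
                 angle = 2 * pi * (seq_len(k) - 1) / k,
                 stringsAsFactors = FALSE)
    }))
  }
}

#' Build the seeded release schedule
#'
#' Expands a [release_protocol()] into one row per released particle: release
#' time, inlet, initial position (with seeded in-plane Gaussian jitter) and
#' initial velocity (`injection_speed` directed into the vessel). Identical
#' protocol, network and config (including seed) give identical schedules.
#'
#' @param protocol a [release_protocol()].
#' @param net a [vascular_network()].
#' @param config a [sim_config()] (supplies `dt` and the jitter seed).
#' @return data frame with columns `particle_id`, `time`, `inlet`, `site`,
#'   `x_mm`, `y_mm`, `z_mm`, `vx`, `vy`, `vz`.
#' @export
make_release_schedule <- function(protocol, net, config = sim_config()) {
  sites <- protocol$sites %||% default_sites(protocol$mode, net)
  inlets <- nodes_of_kind(net, "inlet")
  bad <- setdiff(unique(sites$inlet), inlets)
  if (length(bad))
    stop("release site on non-inlet node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  geom <- lapply(seq_len(nrow(sites)), function(i) {
    nid <- sites$inlet[i]
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    cl <- seg$centerline_mm
    if (seg$proximal == nid) {
      origin <- cl[1, ]; tangent <- unit(cl[2, ] - cl[1, ])
    } else {
      n <- nrow(cl); origin <- cl[n, ]; tangent <- unit(cl[n - 1, ] - cl[n, ])
    }
    basis <- plane_basis(tangent)
    list(origin = origin, tangent = tangent, e1 = basis$e1, e2 = basis$e2,
         radius = seg$radius_mm)
  })
  steps <- seq_len(protocol$window_steps)
  reps <- protocol$particles_per_site_per_step
  n_total <- length(steps) * nrow(sites) * reps
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  rows <- vector("list", n_total)
  k <- 0L
  for (st in steps) {
    for (i in seq_len(nrow(sites))) {
      gi <- geom[[i]]
      for (r in seq_len(reps)) {
        k <- k + 1L
        # nominal in-plane offset plus seeded jitter, clamped inside the wall
        off <- sites$radial_fraction[i] * gi$radius *
          (cos(sites$angle[i]) * gi$e1 + sin(sites$angle[i]) * gi$e2)
        jit <- protocol$jitter_sd * gi$radius
        off <- off + rnorm(1, 0, jit) * gi$e1 + rnorm(1, 0, jit) * gi$e2
        if (vnorm(off) > 0.98 * gi$radius) off <- off * (0.98 * gi$radius / vnorm(off))
        # nudge slightly downstream of the inlet plane so the start is interior
        pos <- gi$origin + off + gi$tangent * (1e-3 * gi$radius)
        vel <- protocol$injection_speed * gi$tangent
        rows[[k]] <- data.frame(
          particle_id = k, time = (st - 1) * config$dt,
          inlet = sites$inlet[i], site = i,
          x_mm = pos[1], y_mm = pos[2], z_mm = pos[3],
          vx = vel[1], vy = vel[2], vz = vel[3])
      }
    }
  }
  sched <- do.call(rbind, rows)
  attr(sched, "mode") <- protocol$mode
  sched
}
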