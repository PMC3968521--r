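test_that("a particle in a uniform co-moving fluid moves in a straight line at constant velocity", {
  spec <- particle_case("B2")
  cfg <- sim_config(gravity = c(0, 0, 0))
  res <- track_free(spec, config = cfg, u_fluid = c(0.2, 0, 0),
                    v0 = c(0.2, 0, 0), duration = 1)
  expect_equal(res$velocity, c(0.2, 0, 0), tolerance = 1e-12)
  expect_equal(res$position_m, c(0.2, 0, 0), tolerance = 1e-9)
  expect_true(all(abs(res$speeds - 0.2) < 1e-12))
})

test_that("settling in quiescent fluid reaches the drag-buoyancy balance speed", {
  # heavy 200 um particle: integrator vs the independent root-finding oracle
  # and, in the small-Re regime, the analytic Stokes form
  spec <- particle_spec(200e-6, 1300)
  res <- track_free(spec, duration = 0.5)
  v_term <- sqrt(sum(res$velocity^2))
  v_oracle <- oracle_terminal_speed(200e-6, 1300)
  expect_lt(abs(v_term - v_oracle) / v_oracle, 5e-3)
  # the analytic Stokes speed is 1.66e-3 m/s; the settling Reynolds number is
  # ~0.11, where the Schiller-Naumann correction lowers the speed by exactly
  # 0.15 Re^0.687 (~3.2%)
  v_stokes <- oracle_stokes_speed(200e-6, 1300)
  expect_equal(v_stokes, 1.662e-3, tolerance = 1e-3)
  re <- slip_reynolds(spec, fluid_properties(), v_oracle)
  expect_lt(abs(v_term - v_stokes) / v_stokes, 0.15 * re^0.687 + 0.005)
  # settling is downward for a heavy particle, upward for a buoyant one
  expect_lt(res$velocity[3], 0)
  up <- track_free(particle_spec(200e-6, 800), duration = 0.5)
  expect_gt(up$velocity[3], 0)
})

test_that("terminal settling matches the force-balance oracle for every study case", {
  tab <- table2_cases()
  for (i in seq_len(nrow(tab))) {
    spec <- particle_spec(tab$diameter_um[i] * 1e-6, tab$density[i])
    res <- track_free(spec, duration = 1)
    v_o <- oracle_terminal_speed(spec$diameter, spec$density)
    expect_lt(abs(sqrt(sum(res$velocity^2)) - v_o) / v_o, 5e-3,
              label = paste("terminal speed", tab$case[i]))
  }
})

test_that("a neutrally buoyant tracer follows the tube axis at the centerline speed", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 260, radius_mm = 2,
                                direction = c(0, 0, 1))
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = 0.025))
  spec <- particle_spec(10e-6, fluid$density)
  st <- particle_state(c(0, 0, 0.01), velocity = c(0, 0, 0.05))
  cfg <- sim_config(t_total = 5)
  fl <- embotrack:::flatten_network(tube, sol)
  res <- embotrack:::cpp_track_particle(
    fl$pts, fl$seg_ptr, fl$radius, fl$mean_vel, fl$dpds, fl$terminal,
    fl$jn_pos, fl$jn_R, fl$port_ptr, fl$port_pos, fl$port_q, fl$port_dir,
    c(0, 0, 0.01e-3), c(0, 0, 0.05), 0, 5, cfg$dt,
    spec$diameter, spec$density, fluid$density, fluid$viscosity,
    cfg$gravity, cfg$c_vm, 0.44, 1, 1, cfg$substep_factor)
  expect_equal(res$status, 0L)  # still inside the long tube after 5 s
  lateral <- sqrt(res$x_end[1]^2 + res$x_end[2]^2)
  expect_lt(lateral, 1e-6)                       # stays on the axis (< 1 um)
  expect_equal(res$v_end[3], 0.05, tolerance = 1e-3)  # centerline speed, 0.1%
  expect_equal(res$x_end[3], 0.01e-3 + 0.05 * 5, tolerance = 1e-4)
})

test_that("step_particle advances a particle by one outer time step", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 100, radius_mm = 2,
                                direction = c(0, 0, 1))
  sol <- solve_flow(tube, fluid, boundary_spec(tube))
  spec <- particle_case("B2")
  st <- particle_state(c(0, 0, 1), velocity = c(0, 0, 0.2))
  cfg <- sim_config(gravity = c(0, 0, 0))
  st2 <- step_particle(st, spec, tube, sol, fluid, cfg)
  expect_equal(st2$time, st$time + cfg$dt)
  expect_gt(st2$position_mm[3], st$position_mm[3])
  expect_gt(st2$path_length_m, 0)
  expect_equal(st2$status, "active")
  st3 <- step_particle(st2, spec, tube, sol, fluid, cfg)
  expect_equal(st3$time, st$time + 2 * cfg$dt)
})

test_that("every released particle is accounted for and records are internally consistent", {
  b <- default_build()
  recs <- run_particles(b$network, b$solution, particle_case("B2"),
                        release_protocol("core", window_steps = 20L),
                        sim_config(seed = 4L))
  expect_length(recs, 60L)
  s <- summarize_records(recs)
  expect_equal(nrow(s), sum(s$status %in% c("exited", "trapped", "deposited")))
  # path length >= net displacement for every record
  for (r in recs) {
    disp <- sqrt(sum((r$positions_mm[nrow(r$positions_mm), ] -
                      r$positions_mm[1, ])^2)) * 1e-3
    expect_gte(r$path_m + 1e-12, disp)
  }
  # exited records carry a valid outlet id
  ex <- s[s$status == "exited", ]
  expect_true(all(ex$outlet %in% nodes_of_kind(b$network, "outlet")))
  expect_true(all(ex$residence_s > 0))
})

test_that("tracking is deterministic: same schedule, config and seed give identical records", {
  b <- default_build()
  run <- function() run_particles(b$network, b$solution, particle_case("A2"),
                                  release_protocol("core", window_steps = 10L),
                                  sim_config(seed = 9L))
  expect_identical(run(), run())
})

test_that("tracer-limit: axis deviation shrinks as the particle size decreases", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 80, radius_mm = 2,
                                direction = c(0, 1, 0))  # horizontal: gravity acts
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = 0.2))
  cfg <- sim_config(t_total = 0.2)
  dev <- vapply(c(400e-6, 100e-6, 25e-6), function(phi) {
    spec <- particle_spec(phi, 1300)
    fl <- embotrack:::flatten_network(tube, sol)
    res <- embotrack:::cpp_track_particle(
      fl$pts, fl$seg_ptr, fl$radius, fl$mean_vel, fl$dpds, fl$terminal,
      fl$jn_pos, fl$jn_R, fl$port_ptr, fl$port_pos, fl$port_q, fl$port_dir,
      c(0, 0.01e-3, 0), c(0, 0.4, 0), 0, 0.2, cfg$dt,
      spec$diameter, spec$density, fluid$density, fluid$viscosity,
      cfg$gravity, cfg$c_vm, 0.44, 1, 1, cfg$substep_factor)
    sqrt(res$x_end[1]^2 + res$x_end[3]^2)
  }, 0)
  expect_true(all(diff(dev) < 0))  # deviation decreases monotonically with size
})

test_that("near-wall releases are slower on average than core releases", {
  b <- default_build()
  core <- run_particles(b$network, b$solution, particle_case("B2"),
                        release_protocol("core", window_steps = 30L),
                        sim_config(seed = 2L))
  wall <- run_particles(b$network, b$solution, particle_case("B2"),
                        release_protocol("near_wall", window_steps = 15L),
                        sim_config(seed = 2L))
  ms <- function(rs) {
    s <- summarize_records(rs)
    mean(s$avg_speed_m_s[s$status == "exited"])
  }
  expect_lt(ms(wall), ms(core))
})
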