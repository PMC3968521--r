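# minimal hand-built trajectory records for metric unit tests
make_record <- function(id = 1L, status = "exited", outlet = "R_MCA_O1",
                        path_m = 1, residence_s = 5, inlet = "R_ICA_in",
                        times = NULL, positions = NULL, speeds = NULL) {
  if (is.null(times)) {
    times <- seq(0, residence_s, length.out = 11)
    positions <- cbind(seq(0, path_m / 1e-3, length.out = 11), 0, 0)
    speeds <- rep(path_m / residence_s, 11)
  }
  structure(list(particle_id = id, case = "B2", release_inlet = inlet,
                 release_mode = "core", release_time = 0, times = times,
                 positions_mm = positions, speeds = speeds, status = status,
                 outlet = outlet, path_m = path_m, residence_s = residence_s,
                 bounces = 0L),
            class = "trajectory_record")
}

test_that("average speed is path length over residence time", {
  r <- make_record(path_m = 1, residence_s = 5)
  expect_equal(average_speed(r), 0.2)
  expect_error(average_speed(make_record(status = "trapped", outlet = NA)),
               "exited particles only")
  # agrees with a trapezoidal re-integration of the sampled speeds within 2%
  b <- default_build()
  recs <- run_particles(b$network, b$solution, particle_case("B2"),
                        release_protocol("core", window_steps = 10L),
                        sim_config(seed = 6L))
  ex <- recs[vapply(recs, `[[`, "", "status") == "exited"]
  for (r in ex[seq_len(min(5, length(ex)))]) {
    tt <- r$times; vv <- r$speeds
    twm <- sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / (max(tt) - min(tt))
    expect_equal(average_speed(r), twm, tolerance = 0.02)
  }
})

test_that("exit distributions normalize over exited particles and match a direct tally", {
  b <- default_build()
  recs <- list(make_record(1, outlet = "R_MCA_O1"),
               make_record(2, outlet = "R_MCA_O1"),
               make_record(3, outlet = "ACA_O2"),
               make_record(4, status = "trapped", outlet = NA),
               make_record(5, outlet = "L_PCA_O"))
  d <- exit_distribution(recs, "outlet")
  expect_equal(sum(d$percentages), 100, tolerance = 1e-8)
  expect_equal(unname(d$percentages["R_MCA_O1"]), 50)
  expect_equal(d$n_trapped, 1L)
  dt <- exit_distribution(recs, "territory", b$network)
  expect_equal(unname(dt$percentages[c("ACA", "BA_PCA", "MCA")]), c(25, 25, 50))
  ds <- exit_distribution(recs, "side", b$network)
  expect_equal(unname(ds$percentages[c("left", "midline", "right")]), c(25, 25, 50))
  # single record: 100% in its outlet
  d1 <- exit_distribution(list(make_record(1)), "outlet")
  expect_equal(unname(d1$percentages), 100)
  # no exits: explicit empty flag
  d0 <- exit_distribution(list(make_record(1, status = "trapped", outlet = NA)),
                          "outlet")
  expect_true(d0$empty)
  expect_length(d0$percentages, 0)
})

test_that("histograms are normalized, order-invariant and use half-open bins", {
  recs <- lapply(1:10, function(i) make_record(i, path_m = 0.2 * 5, residence_s = 5))
  h <- speed_histogram(recs)  # all speeds identical -> one nonzero bin
  expect_equal(sum(h$frequencies), 1, tolerance = 1e-8)
  expect_equal(sum(h$frequencies > 0), 1L)
  # a sample exactly on an internal edge lands in the upper bin
  recs2 <- list(make_record(1, path_m = 0.0125, residence_s = 1),   # 0.0125 m/s
                make_record(2, path_m = 0.025, residence_s = 1),    # on the edge
                make_record(3, path_m = 0.030, residence_s = 1))
  h2 <- speed_histogram(recs2, width = 0.025)
  expect_equal(h2$edges, c(0, 0.025, 0.05))
  expect_equal(h2$frequencies, c(1 / 3, 2 / 3))
  # order invariance
  h3 <- speed_histogram(rev(recs2), width = 0.025)
  expect_identical(h2, h3)
  # residence-time histogram
  ht <- time_histogram(recs, width = 0.1)
  expect_equal(sum(ht$frequencies), 1, tolerance = 1e-8)
  expect_error(speed_histogram(recs, width = 0), "> 0")
})

test_that("tortuosity measures percent excess over the centerline route", {
  expect_equal(tortuosity(make_record(path_m = 0.1), route_length_mm = 100), 0)
  expect_equal(tortuosity(make_record(path_m = 0.11), route_length_mm = 100), 10)
  expect_error(tortuosity(make_record(path_m = 0.1), route_length_mm = 0), "> 0")
  expect_error(tortuosity(make_record(status = "trapped", outlet = NA), 100),
               "exited")
  # a tracer in a straight tube travels essentially the centerline: |T| < 0.1%
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 60, radius_mm = 2,
                                direction = c(0, 0, 1))
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = 0.1))
  spec <- particle_spec(10e-6, fluid$density)
  prot <- release_protocol("core", sites = data.frame(
    inlet = "in", radial_fraction = 0, angle = 0), jitter_sd = 0,
    window_steps = 1L, injection_speed = 0.2)
  recs <- run_particles(tube, sol, spec, prot, sim_config(seed = 1L))
  expect_equal(recs[[1]]$status, "exited")
  tort <- tortuosity(recs[[1]], route_length(tube, "in", "out"))
  expect_lt(abs(tort), 0.1)
})

test_that("case_report assembles consistent per-case tables", {
  b <- default_build()
  sets <- lapply(c("A2", "B2"), function(case)
    run_particles(b$network, b$solution, particle_case(case),
                  release_protocol("core", window_steps = 10L),
                  sim_config(seed = 8L)))
  rep <- case_report(sets, b$network)
  expect_equal(nrow(rep$case_stats), 2L)
  expect_setequal(rep$case_stats$case, c("A2", "B2"))
  expect_equal(rep$case_stats$n_released, c(30L, 30L))
  expect_equal(rep$case_stats$n_released,
               rep$case_stats$n_exited + rep$case_stats$n_trapped +
               rep$case_stats$n_deposited)
  # per-territory rows agree with exit_distribution on the same records
  b2 <- rep$exit_by_territory[rep$exit_by_territory$case == "B2", ]
  expect_equal(nrow(b2), 3L)  # one row per release inlet
  d <- exit_distribution(sets[[2]], "territory", b$network)
  pooled <- sum(b2$MCA * b2$n_exited) / sum(b2$n_exited)
  expect_equal(pooled, unname(d$percentages["MCA"]), tolerance = 1e-9)
  # tortuosity table covers only exited routes and is finite
  expect_true(all(is.finite(rep$tortuosity_by_route$tortuosity_pct)))
  expect_true(all(rep$tortuosity_by_route$tortuosity_pct > -100))
})
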