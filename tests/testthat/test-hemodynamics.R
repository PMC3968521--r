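test_that("segment resistance follows 8 mu L / (pi r^4)", {
  fluid <- fluid_properties()
  seg <- vessel_segment("s", "a", "b", 1, "FEEDING", "internal",
                        rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(segment_resistance(seg, fluid),
               8 * 3.2e-3 * 0.01 / (pi * (1e-3)^4))
  expect_equal(segment_resistance(seg, fluid), 8.149e7, tolerance = 1e-4)
  seg2 <- vessel_segment("s", "a", "b", 1, "FEEDING", "internal",
                         rbind(c(0, 0, 0), c(0, 0, 20)))
  expect_equal(segment_resistance(seg2, fluid), 2 * segment_resistance(seg, fluid))
  seg3 <- vessel_segment("s", "a", "b", 0.5, "FEEDING", "internal",
                         rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(segment_resistance(seg3, fluid), 16 * segment_resistance(seg, fluid))
})

test_that("single-tube solve matches the Hagen-Poiseuille closed form", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 10, radius_mm = 1)
  # impose the inflow that produces a 100 Pa end-to-end drop
  R <- segment_resistance(tube$segments$tube, fluid)
  q_target <- 100 / R
  v_in <- q_target / (pi * (1e-3)^2)
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = v_in))
  expect_equal(sol$segment_flow[["tube"]], 1.227e-6, tolerance = 1e-3)
  expect_equal(sol$node_pressure[["in"]] - sol$node_pressure[["out"]], 100,
               tolerance = 1e-12)
  expect_equal(sol$segment_flow[["tube"]], q_target, tolerance = 1e-12)
})

test_that("a mirror-symmetric Y splits the flow exactly 50/50", {
  net <- make_symmetric_y()
  sol <- solve_flow(net, fluid_properties(), boundary_spec(net))
  expect_equal(sol$segment_flow[["left"]], sol$segment_flow[["right"]],
               tolerance = 1e-14)
  fr <- outlet_fractions(net, sol)
  expect_equal(unname(fr$outlet["out_L"]), 50, tolerance = 1e-10)
})

test_that("junction flow conservation holds to 1e-10 relative on the default network", {
  b <- default_build()
  expect_lt(max_junction_imbalance(b$network, b$solution), 1e-10)
  fr <- outlet_fractions(b$network, b$solution)
  expect_equal(sum(fr$outlet), 100, tolerance = 1e-8)
})

test_that("fixed-flow (M1) boundary conditions honor every prescription", {
  b <- default_build()
  fluid <- fluid_properties()
  bc1 <- m1_boundary(b$network, fluid, b$bc)
  sol1 <- solve_flow(b$network, fluid, bc1)
  for (nm in names(bc1$fixed_outlet_flows)) {
    seg <- Filter(function(s) s$proximal == nm || s$distal == nm,
                  b$network$segments)[[1]]
    expect_equal(sol1$segment_flow[[seg$id]], bc1$fixed_outlet_flows[[nm]],
                 tolerance = 1e-12)
  }
  fr1 <- outlet_fractions(b$network, sol1)
  expect_equal(unname(sum(fr1$territory[c("MCA_R", "MCA_L")])), 60,
               tolerance = 1e-6)
  expect_lt(max_junction_imbalance(b$network, sol1), 1e-10)
})

test_that("boundary_spec validates coverage and the pressure reference", {
  net <- make_symmetric_y()
  expect_error(boundary_spec(net, inlet_velocity = c(bogus = 0.2)),
               "every relevant node")
  expect_error(
    boundary_spec(net, fixed_outlet_flows = c(out_L = 1e-6)),
    "pressure_reference")
  expect_error(
    boundary_spec(net, fixed_outlet_flows = c(out_L = 1e-6),
                  pressure_reference = "in"),
    "not an outlet")
  expect_error(
    boundary_spec(net, fixed_outlet_flows = c(out_L = 1e-6, out_R = 1e-6),
                  pressure_reference = "out_R"),
    "every outlet except")
})

test_that("the in-tube velocity field is the axial Poiseuille profile", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 50, radius_mm = 2,
                                direction = c(0, 0, 1))
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = 0.3906))
  mid <- c(0, 0, 25)
  v_axis <- velocity_at(tube, sol, mid)
  expect_equal(v_axis, c(0, 0, 2 * 0.3906), tolerance = 1e-9)
  expect_equal(sqrt(sum(v_axis^2)), 0.781, tolerance = 1e-3)
  # half-radius point: 1.5 x mean; wall point: no slip
  v_half <- velocity_at(tube, sol, mid + c(1, 0, 0))
  expect_equal(v_half[3], 1.5 * 0.3906, tolerance = 1e-9)
  v_wall <- velocity_at(tube, sol, mid + c(2, 0, 0))
  expect_equal(sqrt(sum(v_wall^2)), 0, tolerance = 1e-12)
  expect_error(velocity_at(tube, sol, mid + c(3, 0, 0)), "outside the lumen")
})

test_that("cross-section quadrature of the velocity field recovers the flow rate", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 50, radius_mm = 1.5,
                                direction = c(0, 0, 1))
  sol <- solve_flow(tube, fluid, boundary_spec(tube))
  r <- 1.5e-3
  # midpoint rule on a polar grid (area-weighted annuli)
  nr <- 30L; na <- 24L
  q <- 0
  for (i in seq_len(nr)) {
    s <- (i - 0.5) / nr * r
    dA <- (2 * pi * s) * (r / nr) / na
    for (k in seq_len(na)) {
      th <- 2 * pi * (k - 0.5) / na
      p_mm <- c(s * cos(th), s * sin(th), 0.025) / 1e-3
      p_mm[3] <- 25
      q <- q + velocity_at(tube, sol, p_mm)[3] * dA
    }
  }
  expect_equal(q, sol$segment_flow[["tube"]], tolerance = 5e-3)
})

test_that("the pressure gradient is uniform, correctly scaled, and points downstream", {
  fluid <- fluid_properties()
  tube <- straight_tube_network(length_mm = 10, radius_mm = 1,
                                direction = c(0, 0, 1))
  R <- segment_resistance(tube$segments$tube, fluid)
  v_in <- (100 / R) / (pi * 1e-6)
  sol <- solve_flow(tube, fluid, boundary_spec(tube, inlet_velocity = v_in))
  g <- pressure_gradient_at(tube, sol, c(0, 0, 5))
  expect_equal(sqrt(sum(g^2)), 1e4, tolerance = 1e-9)   # 100 Pa over 10 mm
  v <- velocity_at(tube, sol, c(0, 0, 5))
  expect_lt(sum(g * v), 0)  # pressure falls along the flow
  # sign check across the default network, probing each long segment at a
  # point on its axis away from the junction mixing regions
  b <- default_build()
  qs <- b$solution$segment_flow
  for (sid in names(qs)[abs(qs) > 1e-12]) {
    seg <- b$network$segments[[sid]]
    if (segment_length(seg) < 8) next
    cl <- seg$centerline_mm
    mid <- cl[1, ] + 0.5 * (cl[2, ] - cl[1, ])
    if (min(sqrt(sum((mid - cl[1, ])^2)),
            sqrt(sum((mid - cl[nrow(cl), ])^2))) < 3) next
    gp <- tryCatch(pressure_gradient_at(b$network, b$solution, mid),
                   error = function(e) NULL)
    if (is.null(gp)) next
    vv <- velocity_at(b$network, b$solution, mid)
    if (sqrt(sum(vv^2)) > 1e-9) expect_lt(sum(gp * vv), 0)
  }
})

test_that("wall distance and outward normal are radial inside a tube", {
  tube <- straight_tube_network(length_mm = 20, radius_mm = 1,
                                direction = c(0, 0, 1))
  wd <- wall_distance(tube, c(0, 0, 10))
  expect_equal(wd$distance_mm, 1, tolerance = 1e-12)
  wd2 <- wall_distance(tube, c(0.9, 0, 10))
  expect_equal(wd2$distance_mm, 0.1, tolerance = 1e-9)
  expect_equal(wd2$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_error(wall_distance(tube, c(2, 0, 10)), "outside the lumen")
})

test_that("removing a zero-flow communicating bridge leaves outlet fractions unchanged", {
  fluid <- fluid_properties()
  h2 <- make_symmetric_h(n_bridges = 2L)
  sol2 <- solve_flow(h2, fluid, boundary_spec(h2))
  expect_lt(abs(sol2$segment_flow[["bridge2"]]), 1e-20 + 1e-12 * sol2$total_inflow)
  # drop the (zero-flow) upper bridge and re-solve
  h1 <- h2
  h1$segments[["bridge2"]] <- NULL
  sol1 <- solve_flow(h1, fluid, boundary_spec(h1))
  f2 <- outlet_fractions(h2, sol2)
  f1 <- outlet_fractions(h1, sol1)
  expect_equal(f1$outlet, f2$outlet, tolerance = 1e-10)
})

test_that("a disconnected network is rejected with an island diagnostic", {
  nodes <- list(network_node("a", c(0, 0, 0), "inlet"),
                network_node("b", c(0, 0, 10), "outlet"),
                network_node("c", c(50, 0, 0), "inlet"),
                network_node("d", c(50, 0, 10), "outlet"))
  segs <- list(
    vessel_segment("s1", "a", "b", 1, "FEEDING", "terminal",
                   rbind(c(0, 0, 0), c(0, 0, 10))),
    vessel_segment("s2", "c", "d", 1, "FEEDING", "terminal",
                   rbind(c(50, 0, 0), c(50, 0, 10))))
  expect_error(vascular_network(nodes, segs), "disconnected")
})
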