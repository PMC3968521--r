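test_that("the complete generator produces the expected inlets and 21 named outlets", {
  net <- generate_cow(cow_variant_spec("complete"))
  expect_setequal(nodes_of_kind(net, "inlet"), c("L_ICA_in", "R_ICA_in", "BA_in"))
  expect_setequal(
    nodes_of_kind(net, "outlet"),
    c(paste0("R_MCA_O", 1:6), paste0("L_MCA_O", 1:4), paste0("ACA_O", 1:6),
      "BAS_O1", "BAS_O2", "L_PCA_O", "R_PCA_O1", "R_PCA_O2"))
  # right/left asymmetry: larger right ICA, six vs four MCA outlets
  expect_gt(net$segments$R_ICA$radius_mm, net$segments$L_ICA$radius_mm)
  # non-terminal trunk diameters inside the anatomical 1-4 mm range
  trunk <- Filter(function(s) s$role != "terminal", net$segments)
  d <- vapply(trunk, function(s) 2 * s$radius_mm, 0)
  expect_true(all(d >= 1 & d <= 4))
})

test_that("generation is deterministic and validates its invariants", {
  a <- generate_cow(cow_variant_spec("complete", seed = 5L))
  b <- generate_cow(cow_variant_spec("complete", seed = 5L))
  expect_identical(a, b)
  expect_silent(validate_network(a))
  # every outlet reachable from every inlet
  g <- embotrack:::network_graph(a)
  d <- igraph::distances(g, v = nodes_of_kind(a, "inlet"),
                         to = nodes_of_kind(a, "outlet"))
  expect_true(all(is.finite(d)))
})

test_that("variant networks differ from complete by exactly one segment", {
  complete <- generate_cow("complete")
  for (v in c("no_L_PCoA", "no_R_ACoA")) {
    vn <- generate_cow(v)
    expect_equal(length(vn$segments), length(complete$segments) - 1L)
    missing <- setdiff(names(complete$segments), names(vn$segments))
    expect_equal(missing, sub("no_", "", v))
    g <- embotrack:::network_graph(vn)
    d <- igraph::distances(g, v = nodes_of_kind(vn, "inlet"),
                           to = nodes_of_kind(vn, "outlet"))
    expect_true(all(is.finite(d)))
  }
  expect_error(generate_cow("no_basilar"), "unknown circle-of-Willis variant")
})

test_that("extend_inlets prolongs only the inlet segments by factor x diameter", {
  net <- generate_cow("complete")
  ext <- extend_inlets(net, 10)
  for (sid in names(net$segments)) {
    s0 <- net$segments[[sid]]; s1 <- ext$segments[[sid]]
    if (s0$role == "inlet") {
      expect_equal(segment_length(s1), segment_length(s0) + 10 * 2 * s0$radius_mm)
    } else {
      expect_identical(s1, s0)  # bit-identical non-inlet geometry
    }
  }
  expect_identical(extend_inlets(net, 0), net)
  expect_error(extend_inlets(net, -1), "non-negative")
})

test_that("route_length sums centerline polylines along the shortest path", {
  tube <- straight_tube_network(length_mm = 10)
  expect_equal(route_length(tube, "in", "out"), 10)
  # two chained segments: 10 + 5
  nodes <- list(network_node("a", c(0, 0, 0), "inlet"),
                network_node("b", c(0, 0, 10), "junction"),
                network_node("c", c(0, 5, 10), "outlet"))
  segs <- list(
    vessel_segment("s1", "a", "b", 1, "FEEDING", "inlet",
                   rbind(c(0, 0, 0), c(0, 0, 10))),
    vessel_segment("s2", "b", "c", 1, "MCA_R", "terminal",
                   rbind(c(0, 0, 10), c(0, 5, 10))))
  chain <- vascular_network(nodes, segs)
  expect_equal(route_length(chain, "a", "c"), 15)
  # polyline route equals the brute-force chord sum
  net <- generate_cow("complete")
  expected <- segment_length(net$segments$BA) +
    segment_length(net$segments$L_PCA_P1) +
    segment_length(net$segments$L_PCA_O)
  expect_equal(route_length(net, "BA_in", "L_PCA_O"), expected)
  # route length is at least the straight-line node distance
  for (out in c("R_MCA_O1", "ACA_O3", "L_PCA_O")) {
    straight <- sqrt(sum((net$nodes$R_ICA_in$position -
                          net$nodes[[out]]$position)^2))
    expect_gte(route_length(net, "R_ICA_in", out), straight)
  }
  expect_error(route_length(net, "nope", "R_MCA_O1"), "unknown node")
})

test_that("locate reports the containing segment, axis position and radial distance", {
  net <- generate_cow("complete")
  # a point on the BA centerline, 10 mm along
  loc <- locate(net, c(0, -22, -18))
  expect_equal(loc$segment, "BA")
  expect_equal(loc$radial_mm, 0, tolerance = 1e-12)
  expect_equal(loc$axial_mm, 10, tolerance = 1e-9)
  # outside: further than 1.5 radii from every axis
  expect_true(isTRUE(locate(net, c(0, -22, -18) + c(1.5 * 1.3, 0, 0))$outside))
  # junction overlap: nearest axis wins, matching the brute-force oracle
  p <- c(0.4, -18.2, 0.3)  # just distal to the basilar bifurcation
  loc <- locate(net, p)
  expect_false(isTRUE(loc$outside))
  oracle <- oracle_nearest_segment(net, p)
  expect_equal(loc$segment, oracle$segment)
  expect_equal(loc$radial_mm, oracle$dist, tolerance = 1e-9)
})

test_that("calibration reaches the requested territory split and only rescales terminals", {
  net <- extend_inlets(generate_cow("complete"), 10)
  fluid <- fluid_properties()
  bc <- boundary_spec(net)
  cal <- calibrate_terminals(net, fluid, bc,
                             c(ACA = 20, MCA = 60, POSTERIOR = 20), tol = 1)
  expect_true(all(abs(cal$achieved - c(ACA = 20, MCA = 60, POSTERIOR = 20)) <= 1))
  # independent re-solve confirms the achieved fractions
  sol2 <- solve_flow(cal$network, fluid, bc)
  fr2 <- outlet_fractions(cal$network, sol2)
  expect_equal(sum(fr2$territory[c("MCA_R", "MCA_L")]), cal$achieved[["MCA"]],
               tolerance = 1e-10)
  # trunk vessels never rescaled
  for (sid in names(net$segments))
    if (net$segments[[sid]]$role != "terminal")
      expect_identical(cal$network$segments[[sid]]$radius_mm,
                       net$segments[[sid]]$radius_mm)
  # a target equal to the achieved state is a fixed point (zero radius change)
  achieved_target <- cal$achieved / sum(cal$achieved) * 100
  cal2 <- calibrate_terminals(cal$network, fluid, bc, achieved_target, tol = 1)
  expect_identical(
    vapply(cal2$network$segments, `[[`, 0, "radius_mm"),
    vapply(cal$network$segments, `[[`, 0, "radius_mm"))
  expect_equal(cal2$iterations, 1L)
})

test_that("calibration rejects a territory with no terminal outlets", {
  tube <- straight_tube_network()
  expect_error(
    calibrate_terminals(tube, target_fractions = c(ACA = 100)),
    "no terminal segments")
})
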