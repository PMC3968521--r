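# Independent oracles and small fixture networks used across the test files.
# The oracles deliberately avoid the package's integration/evaluation code
# paths: terminal velocity comes from a 1-D root of the force balance,
# distances from direct vector algebra, route lengths from explicit sums.

# terminal settling speed: root of |F_D(v)| = |F_B| with the capped
# Schiller-Naumann drag, solved by uniroot on the monotone force balance
oracle_terminal_speed <- function(diameter, density, fluid = fluid_properties(),
                                  g = 9.81, cap = 0.44) {
  fb <- pi / 6 * diameter^3 * abs(density - fluid$density) * g
  if (fb == 0) return(0)
  a <- pi * diameter^2 / 4
  fd <- function(v) {
    re <- fluid$density * v * diameter / fluid$viscosity
    beta <- max(3 * pi * fluid$viscosity * diameter * (1 + 0.15 * re^0.687),
                0.5 * cap * fluid$density * a * v)
    beta * v
  }
  uniroot(function(v) fd(v) - fb, c(1e-12, 10), tol = 1e-14)$root
}

# analytic Stokes settling speed (valid only at small slip Reynolds number)
oracle_stokes_speed <- function(diameter, density, fluid = fluid_properties(),
                                g = 9.81) {
  abs(density - fluid$density) * g * diameter^2 / (18 * fluid$viscosity)
}

# brute-force point-to-centerline distance over every segment of a network
oracle_nearest_segment <- function(net, p) {
  best <- list(segment = NA_character_, dist = Inf)
  for (seg in net$segments) {
    cl <- seg$centerline_mm
    for (j in seq_len(nrow(cl) - 1)) {
      a <- cl[j, ]; b <- cl[j + 1, ]
      d <- b - a
      t <- sum((p - a) * d) / sum(d * d)
      t <- min(max(t, 0), 1)
      q <- a + t * d
      dd <- sqrt(sum((p - q)^2))
      if (dd < best$dist) best <- list(segment = seg$id, dist = dd)
    }
  }
  best
}

# symmetric Y: one inlet splitting into two mirror-image daughters
make_symmetric_y <- function(r_parent = 1.5, r_daughter = 1.0) {
  nodes <- list(
    network_node("in", c(0, 0, -20), "inlet"),
    network_node("jn", c(0, 0, 0), "junction"),
    network_node("out_L", c(-10, 0, 10), "outlet"),
    network_node("out_R", c(10, 0, 10), "outlet"))
  segs <- list(
    vessel_segment("parent", "in", "jn", r_parent, "FEEDING", "inlet",
                   rbind(c(0, 0, -20), c(0, 0, 0))),
    vessel_segment("left", "jn", "out_L", r_daughter, "MCA_L", "terminal",
                   rbind(c(0, 0, 0), c(-10, 0, 10))),
    vessel_segment("right", "jn", "out_R", r_daughter, "MCA_R", "terminal",
                   rbind(c(0, 0, 0), c(10, 0, 10))))
  vascular_network(nodes, segs, name = "symmetric_y")
}

# mirror-symmetric "H": two identical inlet->outlet limbs joined by one or
# two bridges, each carrying exactly zero flow by symmetry
make_symmetric_h <- function(n_bridges = 1L) {
  nodes <- list(
    network_node("in_L", c(-10, 0, -20), "inlet"),
    network_node("in_R", c(10, 0, -20), "inlet"),
    network_node("jn_L", c(-10, 0, 0), "junction"),
    network_node("jn_R", c(10, 0, 0), "junction"),
    network_node("out_L", c(-10, 0, 20), "outlet"),
    network_node("out_R", c(10, 0, 20), "outlet"))
  segs <- list(
    limb_in_L = vessel_segment("limb_in_L", "in_L", "jn_L", 1.5, "FEEDING", "inlet",
                   rbind(c(-10, 0, -20), c(-10, 0, 0))),
    limb_in_R = vessel_segment("limb_in_R", "in_R", "jn_R", 1.5, "FEEDING", "inlet",
                   rbind(c(10, 0, -20), c(10, 0, 0))),
    limb_out_L = vessel_segment("limb_out_L", "jn_L", "out_L", 1.2, "MCA_L", "terminal",
                   rbind(c(-10, 0, 0), c(-10, 0, 20))),
    limb_out_R = vessel_segment("limb_out_R", "jn_R", "out_R", 1.2, "MCA_R", "terminal",
                   rbind(c(10, 0, 0), c(10, 0, 20))))
  segs <- c(segs, list(
    vessel_segment("bridge", "jn_L", "jn_R", 0.7, "COMMUNICATING", "internal",
                   rbind(c(-10, 0, 0), c(10, 0, 0)))))
  if (n_bridges > 1L) {
    nodes <- c(nodes, list(network_node("jn_L2", c(-10, 0, 10), "junction"),
                           network_node("jn_R2", c(10, 0, 10), "junction")))
    segs[["limb_out_L"]] <- NULL; segs[["limb_out_R"]] <- NULL
    segs <- c(segs, list(
      vessel_segment("limb_mid_L", "jn_L", "jn_L2", 1.2, "MCA_L", "internal",
                     rbind(c(-10, 0, 0), c(-10, 0, 10))),
      vessel_segment("limb_mid_R", "jn_R", "jn_R2", 1.2, "MCA_R", "internal",
                     rbind(c(10, 0, 0), c(10, 0, 10))),
      vessel_segment("limb_out_L", "jn_L2", "out_L", 1.2, "MCA_L", "terminal",
                     rbind(c(-10, 0, 10), c(-10, 0, 20))),
      vessel_segment("limb_out_R", "jn_R2", "out_R", 1.2, "MCA_R", "terminal",
                     rbind(c(10, 0, 10), c(10, 0, 20))),
      vessel_segment("bridge2", "jn_L2", "jn_R2", 0.7, "COMMUNICATING", "internal",
                     rbind(c(-10, 0, 10), c(10, 0, 10)))))
  }
  vascular_network(nodes, segs, name = "symmetric_h")
}

# default calibrated network, built once per test run
default_build <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_default_network()
    cache
  }
})
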