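TERRITORIES <- c("MCA_R", "MCA_L", "ACA", "POSTERIOR", "FEEDING", "COMMUNICATING")
SEGMENT_ROLES <- c("inlet", "internal", "terminal")
NODE_KINDS <- c("inlet", "junction", "outlet")
COW_VARIANTS <- c("complete", "no_L_PCoA", "no_R_ACoA")

#' Specification of a circle-of-Willis variant
#'
#' @param variant one of `"complete"`, `"no_L_PCoA"` (left posterior
#'   communicating artery absent) or `"no_R_ACoA"` (anterior communicating
#'   segment absent). The two incomplete variants differ from `"complete"` by
#'   exactly one segment.
#' @param diameter_scale multiplier applied to every default vessel radius.
#' @param seed integer recorded with the network for provenance. The default
#'   generator is fully deterministic, so the seed does not currently alter
#'   the geometry; it is kept so that stochastic perturbations added later
#'   remain reproducible.
#' @return an object of class `cow_variant_spec`.
#' @export
cow_variant_spec <- function(variant = "complete", diameter_scale = 1, seed = 1L) {
  if (!is.character(variant) || length(variant) != 1L || !variant %in% COW_VARIANTS)
    stop("unknown circle-of-Willis variant: ", paste(variant, collapse = ", "),
         " (must be one of ", paste(COW_VARIANTS, collapse = ", "), ")", call. = FALSE)
  if (!is.numeric(diameter_scale) || diameter_scale <= 0)
    stop("diameter_scale must be a positive number", call. = FALSE)
  structure(list(variant = variant, diameter_scale = diameter_scale,
                 seed = as.integer(seed)),
            class = "cow_variant_spec")
}

#' Vessel segment constructor
#'
#' A segment is a constant-radius tube around an ordered centerline polyline.
#' Coordinates are millimetres.
#'
#' @param id unique segment identifier.
#' @param proximal,distal node ids of the two ends.
#' @param radius_mm lumen radius in mm (> 0).
#' @param territory one of `r paste(TERRITORIES, collapse=", ")`.
#' @param role `"inlet"`, `"internal"` or `"terminal"`.
#' @param centerline_mm numeric matrix (>= 2 rows) of centerline points in mm;
#'   the first row must coincide with the proximal node position and the last
#'   with the distal node position.
#' @return an object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, proximal, distal, radius_mm, territory, role,
                           centerline_mm) {
  centerline_mm <- as.matrix(centerline_mm)
  storage.mode(centerline_mm) <- "double"
  if (nrow(centerline_mm) < 2L)
    stop("segment '", id, "': centerline needs at least 2 points", call. = FALSE)
  if (any(!is.finite(centerline_mm)))
    stop("segment '", id, "': non-finite centerline coordinate", call. = FALSE)
  steps <- sqrt(rowSums(diff(centerline_mm)^2))
  if (any(steps <= 0))
    stop("segment '", id, "': consecutive centerline points must be distinct",
         call. = FALSE)
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("segment '", id, "': radius must be > 0", call. = FALSE)
  territory <- match.arg(territory, TERRITORIES)
  role <- match.arg(role, SEGMENT_ROLES)
  structure(list(id = as.character(id), proximal = as.character(proximal),
                 distal = as.character(distal), radius_mm = as.numeric(radius_mm),
                 territory = territory, role = role,
                 centerline_mm = unname(centerline_mm)),
            class = "vessel_segment")
}

#' Length of a vessel segment centerline (mm)
#' @param seg a [vessel_segment()].
#' @export
segment_length <- function(seg) polyline_length(seg$centerline_mm)

#' Network node constructor
#' @param id unique node identifier.
#' @param position numeric xyz in mm.
#' @param kind `"inlet"`, `"junction"` or `"outlet"`.
#' @export
network_node <- function(id, position, kind) {
  kind <- match.arg(kind, NODE_KINDS)
  structure(list(id = as.character(id), position = as_point3(position),
                 kind = kind), class = "network_node")
}

#' Assemble and validate a vascular network
#'
#' @param nodes list of [network_node()] objects.
#' @param segments list of [vessel_segment()] objects.
#' @param name character label.
#' @param meta optional list of provenance fields.
#' @return an object of class `vascular_network`.
#' @details Validation enforces: unique ids, segment endpoints coinciding with
#'   their node positions (within 1e-9 mm), inlet and outlet nodes attached to
#'   exactly one segment, junction nodes attached to at least two (a degree-1
#'   junction is accepted as a capped blind stub, which arises when a
#'   communicating artery is removed from a variant network), and a connected
#'   graph.
#' @export
vascular_network <- function(nodes, segments, name = "network", meta = list()) {
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  names(segments) <- vapply(segments, `[[`, "", "id")
  net <- structure(list(nodes = nodes, segments = segments,
                        name = name, meta = meta),
                   class = "vascular_network")
  validate_network(net)
  net
}

#' Validate the structural invariants of a vascular network
#' @param net a [vascular_network()].
#' @return `net` invisibly; stops with a diagnostic on violation.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes; segments <- net$segments
  nid <- names(nodes); sid <- names(segments)
  if (anyDuplicated(nid)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate segment ids", call. = FALSE)
  for (seg in segments) {
    for (endp in c("proximal", "distal")) {
      nd <- nodes[[seg[[endp]]]]
      if (is.null(nd))
        stop("segment '", seg$id, "' references unknown node '", seg[[endp]], "'",
             call. = FALSE)
      pt <- if (endp == "proximal") seg$centerline_mm[1, ]
            else seg$centerline_mm[nrow(seg$centerline_mm), ]
      if (max(abs(pt - nd$position)) > 1e-9)
        stop("segment '", seg$id, "': ", endp,
             " centerline endpoint does not coincide with node '", nd$id, "'",
             call. = FALSE)
    }
  }
  deg <- node_degrees(net)
  for (nd in nodes) {
    d <- deg[[nd$id]]
    if (is.null(d) || is.na(d)) d <- 0L
    if (nd$kind %in% c("inlet", "outlet") && d != 1L)
      stop("node '", nd$id, "' is an ", nd$kind,
           " and must attach to exactly one segment (has ", d, ")", call. = FALSE)
    if (nd$kind == "junction" && d < 1L)
      stop("junction node '", nd$id, "' attaches to no segment", call. = FALSE)
  }
  g <- network_graph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    isl <- names(comp$membership[comp$membership != comp$membership[1]])
    stop("network is disconnected; island containing: ",
         paste(utils::head(isl, 5), collapse = ", "), call. = FALSE)
  }
  invisible(net)
}

#' @noRd
node_degrees <- function(net) {
  ends <- unlist(lapply(net$segments, function(s) c(s$proximal, s$distal)))
  tab <- table(ends)
  out <- setNames(rep(0L, length(net$nodes)), names(net$nodes))
  out[names(tab)] <- as.integer(tab)
  out
}

#' @noRd
network_graph <- function(net) {
  el <- do.call(rbind, lapply(net$segments, function(s) c(s$proximal, s$distal)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight",
    value = vapply(net$segments, segment_length, 0))
  g <- igraph::set_edge_attr(g, "segment", value = names(net$segments))
  # isolated nodes cannot occur (every node is referenced by >= 1 segment after
  # validation), but keep any unreferenced ones visible for diagnostics
  missing <- setdiff(names(net$nodes), igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

#' Node ids by kind
#' @param net a [vascular_network()].
#' @param kind `"inlet"`, `"junction"` or `"outlet"`.
#' @export
nodes_of_kind <- function(net, kind) {
  kind <- match.arg(kind, NODE_KINDS)
  names(Filter(function(n) n$kind == kind, net$nodes))
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", x$name, "\n", sep = "")
  cat("  nodes:    ", length(x$nodes), " (", length(nodes_of_kind(x, "inlet")),
      " inlets, ", length(nodes_of_kind(x, "outlet")), " outlets)\n", sep = "")
  cat("  segments: ", length(x$segments), "\n", sep = "")
  terr <- table(vapply(x$segments, `[[`, "", "territory"))
  cat("  territories:", paste(names(terr), terr, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Default synthetic circle of Willis
# ---------------------------------------------------------------------------

# Blueprint of the default geometry. Coordinates in mm, right-handed frame:
# +x right, +y anterior, +z superior. The feeding arteries ascend (+z) as the
# carotids and basilar do anatomically. The left ICA terminus is a T-shaped
# junction (MCA leaves laterally at ~90 degrees), the right a Y-shape, the
# morphological contrast that drives side-dependent particle routing.
#' @noRd
cow_blueprint <- function() {
  N <- function(id, x, y, z, kind) list(id = id, pos = c(x, y, z), kind = kind)
  nodes <- list(
    N("R_ICA_in", 14, -2, -30, "inlet"),
    N("L_ICA_in", -14, -2, -30, "inlet"),
    N("BA_in", 0, -22, -28, "inlet"),
    N("R_ICA_term", 10, 0, 0, "junction"),
    N("L_ICA_term", -10, 0, 0, "junction"),
    N("BA_top", 0, -18, 0, "junction"),
    N("R_MCA_jn", 24, 2, 5, "junction"),
    N("R_MCA_jn_a", 32, 6, 9, "junction"),
    N("R_MCA_jn_b", 32, -4, 9, "junction"),
    N("L_MCA_jn", -24, 0, 0, "junction"),
    N("L_MCA_jn_a", -32, 4, 6, "junction"),
    N("L_MCA_jn_b", -32, -4, 6, "junction"),
    N("ACA_mid", 0, 14, 4, "junction"),
    N("ACA_jn_R", 2, 13, 4, "junction"),
    N("ACA_jn2", 0, 18, 14, "junction"),
    N("ACA_jn_a", 2, 21, 24, "junction"),
    N("ACA_jn_b", -2, 25, 18, "junction"),
    N("R_PCA_jn", 8, -20, 2, "junction"),
    N("R_PCA_jn2", 14, -24, 4, "junction"),
    N("L_PCA_jn", -8, -20, 2, "junction"),
    N("R_MCA_O1", 42, 10, 12, "outlet"),
    N("R_MCA_O2", 38, 4, 17, "outlet"),
    N("R_MCA_O3", 40, 9, 3, "outlet"),
    N("R_MCA_O4", 42, -9, 12, "outlet"),
    N("R_MCA_O5", 38, -2, 17, "outlet"),
    N("R_MCA_O6", 40, -7, 3, "outlet"),
    N("L_MCA_O1", -42, 9, 11, "outlet"),
    N("L_MCA_O2", -38, 2, 15, "outlet"),
    N("L_MCA_O3", -42, -9, 11, "outlet"),
    N("L_MCA_O4", -38, -3, 15, "outlet"),
    N("ACA_O1", 6, 23, 32, "outlet"),
    N("ACA_O2", 2, 17, 34, "outlet"),
    N("ACA_O3", 5, 29, 28, "outlet"),
    N("ACA_O4", -6, 31, 22, "outlet"),
    N("ACA_O5", -3, 35, 15, "outlet"),
    N("ACA_O6", -7, 27, 12, "outlet"),
    N("BAS_O1", 13, -26, -3, "outlet"),
    N("BAS_O2", -13, -26, -3, "outlet"),
    N("L_PCA_O", -16, -27, 6, "outlet"),
    N("R_PCA_O1", 20, -31, 8, "outlet"),
    N("R_PCA_O2", 22, -25, 11, "outlet")
  )
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  # id, prox, dist, radius_mm, territory, role, optional interior waypoints
  S <- function(id, prox, dist, r, terr, role, via = NULL)
    list(id = id, prox = prox, dist = dist, r = r, terr = terr, role = role,
         via = via)
  segs <- list(
    S("R_ICA", "R_ICA_in", "R_ICA_term", 2.0, "FEEDING", "inlet",
      rbind(c(14, -2, -12), c(12, -1, -5))),
    S("L_ICA", "L_ICA_in", "L_ICA_term", 1.9, "FEEDING", "inlet",
      rbind(c(-14, -2, -12), c(-12, -1, -5))),
    S("BA", "BA_in", "BA_top", 1.3, "FEEDING", "inlet",
      rbind(c(0, -22, -10), c(0, -20, -4))),
    # right MCA tree (Y-shaped take-off from the carotid terminus)
    S("R_MCA_M1", "R_ICA_term", "R_MCA_jn", 1.5, "MCA_R", "internal",
      rbind(c(17, 1, 2.5))),
    S("R_MCA_M2a", "R_MCA_jn", "R_MCA_jn_a", 1.2, "MCA_R", "internal"),
    S("R_MCA_M2b", "R_MCA_jn", "R_MCA_jn_b", 1.2, "MCA_R", "internal"),
    S("R_MCA_O1", "R_MCA_jn_a", "R_MCA_O1", 1.15, "MCA_R", "terminal"),
    S("R_MCA_O2", "R_MCA_jn_a", "R_MCA_O2", 0.85, "MCA_R", "terminal"),
    S("R_MCA_O3", "R_MCA_jn_a", "R_MCA_O3", 0.95, "MCA_R", "terminal"),
    S("R_MCA_O4", "R_MCA_jn_b", "R_MCA_O4", 1.0, "MCA_R", "terminal"),
    S("R_MCA_O5", "R_MCA_jn_b", "R_MCA_O5", 1.05, "MCA_R", "terminal"),
    S("R_MCA_O6", "R_MCA_jn_b", "R_MCA_O6", 0.95, "MCA_R", "terminal"),
    # left MCA tree (T-shaped take-off: M1 leaves the vertical carotid at 90 deg)
    S("L_MCA_M1", "L_ICA_term", "L_MCA_jn", 1.5, "MCA_L", "internal",
      rbind(c(-17, 0, 0))),
    S("L_MCA_M2a", "L_MCA_jn", "L_MCA_jn_a", 1.2, "MCA_L", "internal"),
    S("L_MCA_M2b", "L_MCA_jn", "L_MCA_jn_b", 1.2, "MCA_L", "internal"),
    S("L_MCA_O1", "L_MCA_jn_a", "L_MCA_O1", 1.2, "MCA_L", "terminal"),
    S("L_MCA_O2", "L_MCA_jn_a", "L_MCA_O2", 1.05, "MCA_L", "terminal"),
    S("L_MCA_O3", "L_MCA_jn_b", "L_MCA_O3", 1.0, "MCA_L", "terminal"),
    S("L_MCA_O4", "L_MCA_jn_b", "L_MCA_O4", 1.0, "MCA_L", "terminal"),
    # anterior cerebral tree; the left A1 reaches the midline confluence
    # directly, the right A1 joins it through a short communicating segment
    S("L_ACA_A1", "L_ICA_term", "ACA_mid", 1.2, "ACA", "internal",
      rbind(c(-5, 8, 2))),
    S("R_ACA_A1", "R_ICA_term", "ACA_jn_R", 1.2, "ACA", "internal",
      rbind(c(6, 7, 2))),
    S("R_ACoA", "ACA_jn_R", "ACA_mid", 0.7, "COMMUNICATING", "internal"),
    S("ACA_A2", "ACA_mid", "ACA_jn2", 1.1, "ACA", "internal"),
    S("ACA_br_a", "ACA_jn2", "ACA_jn_a", 0.95, "ACA", "internal"),
    S("ACA_br_b", "ACA_jn2", "ACA_jn_b", 0.95, "ACA", "internal"),
    S("ACA_O1", "ACA_jn_a", "ACA_O1", 0.8, "ACA", "terminal"),
    S("ACA_O2", "ACA_jn_a", "ACA_O2", 0.85, "ACA", "terminal"),
    S("ACA_O3", "ACA_jn_a", "ACA_O3", 0.8, "ACA", "terminal"),
    S("ACA_O4", "ACA_jn_b", "ACA_O4", 0.75, "ACA", "terminal"),
    S("ACA_O5", "ACA_jn_b", "ACA_O5", 0.7, "ACA", "terminal"),
    S("ACA_O6", "ACA_jn_b", "ACA_O6", 0.75, "ACA", "terminal"),
    # posterior circulation
    S("R_PCA_P1", "BA_top", "R_PCA_jn", 1.1, "POSTERIOR", "internal",
      rbind(c(4, -19, 1))),
    S("L_PCA_P1", "BA_top", "L_PCA_jn", 1.1, "POSTERIOR", "internal",
      rbind(c(-4, -19, 1))),
    S("R_PCoA", "R_ICA_term", "R_PCA_jn", 0.7, "COMMUNICATING", "internal",
      rbind(c(9, -10, 1))),
    S("L_PCoA", "L_ICA_term", "L_PCA_jn", 0.7, "COMMUNICATING", "internal",
      rbind(c(-9, -10, 1))),
    S("R_PCA_P2", "R_PCA_jn", "R_PCA_jn2", 1.0, "POSTERIOR", "internal"),
    S("R_PCA_O1", "R_PCA_jn2", "R_PCA_O1", 0.9, "POSTERIOR", "terminal"),
    S("R_PCA_O2", "R_PCA_jn2", "R_PCA_O2", 0.9, "POSTERIOR", "terminal"),
    S("L_PCA_O", "L_PCA_jn", "L_PCA_O", 1.0, "POSTERIOR", "terminal"),
    S("BAS_O1", "BA_top", "BAS_O1", 0.95, "POSTERIOR", "terminal"),
    S("BAS_O2", "BA_top", "BAS_O2", 0.95, "POSTERIOR", "terminal")
  )
  list(nodes = nodes, segments = segs)
}

#' Generate the synthetic circle-of-Willis network
#'
#' Builds an idealized cerebral arterial tube network with three inlets
#' (`L_ICA`, `R_ICA`, `BA`), a complete communicating-artery ring, and 21
#' named terminal outlets (`R_MCA_O1`..`R_MCA_O6`, `L_MCA_O1`..`L_MCA_O4`,
#' `ACA_O1`..`ACA_O6`, `BAS_O1`..`BAS_O2`, `L_PCA_O`, `R_PCA_O1`..`R_PCA_O2`).
#' Trunk vessel diameters lie in the anatomical 1--4 mm range, with the right
#' ICA slightly larger than the left and six right versus four left MCA
#' outlets, mirroring the left/right asymmetry of a typical subject. The
#' generator is deterministic: identical specs produce identical networks.
#'
#' @param spec a [cow_variant_spec()] (or a variant name, which is promoted).
#' @return a [vascular_network()].
#' @examples
#' net <- generate_cow(cow_variant_spec("complete"))
#' length(nodes_of_kind(net, "outlet"))  # 21
#' @export
generate_cow <- function(spec = cow_variant_spec()) {
  if (is.character(spec)) spec <- cow_variant_spec(spec)
  if (!inherits(spec, "cow_variant_spec"))
    stop("spec must be a cow_variant_spec", call. = FALSE)
  bp <- cow_blueprint()
  drop <- switch(spec$variant, complete = character(),
                 no_L_PCoA = "L_PCoA", no_R_ACoA = "R_ACoA")
  nodes <- lapply(bp$nodes, function(n) network_node(n$id, n$pos, n$kind))
  segs <- lapply(bp$segments, function(s) {
    if (s$id %in% drop) return(NULL)
    cl <- rbind(bp$nodes[[s$prox]]$pos,
                if (!is.null(s$via)) s$via,
                bp$nodes[[s$dist]]$pos)
    vessel_segment(s$id, s$prox, s$dist, s$r * spec$diameter_scale,
                   s$terr, s$role, cl)
  })
  segs <- Filter(Negate(is.null), segs)
  vascular_network(nodes, segs,
                   name = paste0("synthetic_cow_", spec$variant),
                   meta = list(variant = spec$variant,
                               diameter_scale = spec$diameter_scale,
                               seed = spec$seed))
}

#' Prolong the inlet vessels upstream
#'
#' Each inlet segment is extended by `factor` times its local diameter along
#' its entry tangent as a straight run (the usual device for letting the
#' inflow profile develop and decoupling the injection plane from the first
#' bend). All other segments are untouched; the inlet node moves with the new
#' entry plane.
#'
#' @param net a [vascular_network()].
#' @param factor non-negative multiple of the local diameter (default 10).
#' @return the extended network.
#' @export
extend_inlets <- function(net, factor = 10) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0)
    stop("factor must be a non-negative number", call. = FALSE)
  if (factor == 0) return(net)
  for (sid in names(net$segments)) {
    seg <- net$segments[[sid]]
    if (seg$role != "inlet") next
    cl <- seg$centerline_mm
    tangent <- unit(cl[2, ] - cl[1, ])
    ext <- factor * 2 * seg$radius_mm
    new_start <- cl[1, ] - tangent * ext
    seg$centerline_mm <- rbind(new_start, cl)
    net$segments[[sid]] <- seg
    net$nodes[[seg$proximal]]$position <- new_start
  }
  validate_network(net)
  net
}

#' Shortest centerline route length between two nodes
#'
#' Polyline length (mm) of the shortest path through the network from
#' `inlet_id` to `outlet_id`, weighting each segment by its centerline length.
#' This is the reference route against which particle path tortuosity is
#' measured.
#'
#' @param net a [vascular_network()].
#' @param inlet_id,outlet_id node ids.
#' @return route length in mm.
#' @export
route_length <- function(net, inlet_id, outlet_id) {
  if (is.null(net$nodes[[inlet_id]]) || is.null(net$nodes[[outlet_id]]))
    stop("unknown node id: ",
         paste(setdiff(c(inlet_id, outlet_id), names(net$nodes)), collapse = ", "),
         call. = FALSE)
  g <- network_graph(net)
  d <- igraph::distances(g, v = inlet_id, to = outlet_id, weights = igraph::E(g)$weight)
  if (!is.finite(d[1, 1]))
    stop("no path between '", inlet_id, "' and '", outlet_id, "'", call. = FALSE)
  as.numeric(d[1, 1])
}

#' Locate a point inside the tube network
#'
#' Reports which lumen segment contains the point. In junction regions where
#' several tubes overlap, the segment whose axis is nearest wins.
#'
#' @param net a [vascular_network()].
#' @param p point in mm.
#' @return a list with `segment`, `axial_mm` (arc-length position along the
#'   centerline) and `radial_mm` (distance from the axis), or
#'   `list(outside = TRUE)` when the point is beyond every tube.
#' @export
locate <- function(net, p) {
  p <- as_point3(p)
  fl <- flatten_network(net)
  res <- cpp_locate(fl$pts, fl$seg_ptr, fl$radius, matrix(p * MM, nrow = 1))
  if (res$inside[1] == 0L) return(list(outside = TRUE))
  idx <- res$segment[1]
  list(segment = names(net$segments)[idx],
       axial_mm = res$axial[1] / MM,
       radial_mm = res$radial[1] / MM)
}

# Flatten the network geometry (and optionally a flow solution) into the
# plain arrays the compiled kernels consume. All quantities in SI units.
#' @noRd
flatten_network <- function(net, sol = NULL) {
  segs <- net$segments
  nseg <- length(segs)
  ptl <- lapply(segs, function(s) s$centerline_mm * MM)
  npts <- vapply(ptl, nrow, 0L)
  seg_ptr <- c(0L, cumsum(npts))
  pts <- do.call(rbind, ptl)
  radius <- vapply(segs, function(s) s$radius_mm * MM, 0)
  terminal <- as.integer(vapply(segs, function(s) s$role == "terminal", FALSE))
  inlet <- as.integer(vapply(segs, function(s) s$role == "inlet", FALSE))
  out <- list(pts = pts, seg_ptr = as.integer(seg_ptr), radius = radius,
              terminal = terminal, inlet = inlet,
              seg_ids = names(segs))
  if (!is.null(sol)) {
    q <- sol$segment_flow[names(segs)]
    area <- pi * radius^2
    out$mean_vel <- as.numeric(q / area)
    len <- vapply(segs, segment_length, 0) * MM
    dp <- sol$node_pressure[vapply(segs, `[[`, "", "distal")] -
          sol$node_pressure[vapply(segs, `[[`, "", "proximal")]
    out$dpds <- as.numeric(dp / len)
    jn <- junction_balls(net, sol)
    out$jn_pos <- jn$pos; out$jn_R <- jn$R
    out$port_ptr <- jn$port_ptr; out$port_pos <- jn$port_pos
    out$port_q <- jn$port_q; out$port_dir <- jn$port_dir
  } else {
    out$mean_vel <- numeric(nseg)
    out$dpds <- numeric(nseg)
    out$jn_pos <- matrix(0, 0, 3); out$jn_R <- numeric(0)
    out$port_ptr <- 0L; out$port_pos <- matrix(0, 0, 3)
    out$port_q <- numeric(0); out$port_dir <- matrix(0, 0, 3)
  }
  out
}

# Junction mixing spheres: each junction node carries a ball (radius 1.05 x
# the largest attached lumen radius) that is part of the lumen. The velocity
# inside the ball superposes, for every attached vessel port (where the vessel
# axis crosses the ball surface, strength = solved signed segment flow):
# a directed, softened jet along the vessel's flow direction for inflow ports,
# and a softened converging point sink for outflow ports (net flux zero by
# conservation). Jets push arriving particles across the ball, sinks collect
# them into the downstream vessels, so no stable stagnation region forms;
# the capped tube profiles take over beyond the ports.
#' @noRd
junction_balls <- function(net, sol) {
  jn <- nodes_of_kind(net, "junction")
  pos <- matrix(0, length(jn), 3)
  R <- numeric(length(jn))
  port_pos <- list(); port_q <- list(); port_dir <- list()
  port_ptr <- integer(length(jn) + 1)
  for (i in seq_along(jn)) {
    nid <- jn[i]
    npos <- net$nodes[[nid]]$position * MM
    pos[i, ] <- npos
    segs <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)
    rmax <- max(vapply(segs, function(s) s$radius_mm, 0)) * MM
    R[i] <- 1.05 * rmax
    pp <- matrix(0, length(segs), 3); pq <- numeric(length(segs))
    pd <- matrix(0, length(segs), 3)
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      cl <- s$centerline_mm
      if (s$proximal == nid) {
        q_away <- sol$segment_flow[[s$id]]
        d_away <- unit(cl[2, ] - cl[1, ])
      } else {
        q_away <- -sol$segment_flow[[s$id]]
        n <- nrow(cl)
        d_away <- unit(cl[n - 1, ] - cl[n, ]) * -1
      }
      pp[k, ] <- npos + d_away * R[i]
      pq[k] <- -q_away      # flow arriving at the node is a source for the ball
      pd[k, ] <- -d_away    # jet direction: into the ball, along the vessel
    }
    port_pos[[i]] <- pp; port_q[[i]] <- pq; port_dir[[i]] <- pd
    port_ptr[i + 1] <- port_ptr[i] + length(segs)
  }
  list(pos = pos, R = R, port_ptr = as.integer(port_ptr),
       port_pos = do.call(rbind, c(port_pos, list(matrix(0, 0, 3)))),
       port_q = unlist(c(port_q, list(numeric(0)))),
       port_dir = do.call(rbind, c(port_dir, list(matrix(0, 0, 3)))))
}

#' Build a single straight-tube network
#'
#' Convenience constructor used for verification against closed-form
#' Hagen--Poiseuille results and streamline-adherence checks.
#'
#' @param length_mm tube length in mm.
#' @param radius_mm tube radius in mm.
#' @param direction unit-ish direction vector of the tube axis.
#' @param origin proximal end position in mm.
#' @return a [vascular_network()] with one inlet node, one outlet node and one
#'   segment named `"tube"`.
#' @export
straight_tube_network <- function(length_mm = 10, radius_mm = 1,
                                  direction = c(0, 0, 1), origin = c(0, 0, 0)) {
  dirn <- unit(as_point3(direction))
  p0 <- as_point3(origin)
  p1 <- p0 + dirn * length_mm
  vascular_network(
    nodes = list(network_node("in", p0, "inlet"),
                 network_node("out", p1, "outlet")),
    segments = list(vessel_segment("tube", "in", "out", radius_mm,
                                   "FEEDING", "terminal", rbind(p0, p1))),
    name = "straight_tube")
}
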