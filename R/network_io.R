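NETWORK_SCHEMA_VERSION <- "1.0"

#' Write a vascular network to JSON
#'
#' Schema: `{schema_version, name, nodes:[{id, kind, xyz_mm}],
#' segments:[{id, proximal, distal, radius_mm, territory, role,
#' centerline_mm:[[x,y,z],...]}]}`. The round trip through [read_network()]
#' is lossless.
#'
#' @param net a [vascular_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(
    schema_version = NETWORK_SCHEMA_VERSION,
    name = net$name,
    nodes = lapply(unname(net$nodes), function(n)
      list(id = n$id, kind = n$kind, xyz_mm = n$position)),
    segments = lapply(unname(net$segments), function(s)
      list(id = s$id, proximal = s$proximal, distal = s$distal,
           radius_mm = s$radius_mm, territory = s$territory, role = s$role,
           centerline_mm = unname(s$centerline_mm)))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a vascular network from JSON
#'
#' @param path file written by [write_network()] or conforming to its schema.
#' @return a [vascular_network()].
#' @export
read_network <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    stop("cannot parse network file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (f in c("schema_version", "name", "nodes", "segments"))
    if (is.null(obj[[f]]))
      stop("network file is missing field '", f, "'", call. = FALSE)
  nodes <- lapply(obj$nodes, function(n) {
    for (f in c("id", "kind", "xyz_mm"))
      if (is.null(n[[f]]))
        stop("node entry is missing field '", f, "'", call. = FALSE)
    network_node(n$id, unlist(n$xyz_mm), n$kind)
  })
  segments <- lapply(obj$segments, function(s) {
    for (f in c("id", "proximal", "distal", "radius_mm", "territory", "role",
                "centerline_mm"))
      if (is.null(s[[f]]))
        stop("segment entry", if (!is.null(s$id)) paste0(" '", s$id, "'"),
             " is missing field '", f, "'", call. = FALSE)
    cl <- do.call(rbind, lapply(s$centerline_mm, unlist))
    vessel_segment(s$id, s$proximal, s$distal, s$radius_mm, s$territory,
                   s$role, cl)
  })
  vascular_network(nodes, segments, name = obj$name,
                   meta = list(schema_version = obj$schema_version))
}

#' Export network centerlines as VTK PolyData (legacy ASCII)
#'
#' Optional visualization helper: writes the segment centerlines as polylines
#' with per-point radius, loadable in ParaView.
#'
#' @param net a [vascular_network()].
#' @param path output `.vtk` file path.
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(net, path) {
  ptl <- lapply(net$segments, function(s) s$centerline_mm)
  npts <- vapply(ptl, nrow, 0L)
  pts <- do.call(rbind, ptl)
  offsets <- c(0L, cumsum(npts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("embotrack centerlines:", net$name),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(pts), "float")), con)
  writeLines(apply(pts, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
  nl <- length(npts)
  writeLines(paste("LINES", nl, nl + sum(npts)), con)
  for (k in seq_len(nl)) {
    ids <- seq.int(offsets[k], offsets[k + 1] - 1L)
    writeLines(paste(c(length(ids), ids), collapse = " "), con)
  }
  rad <- unlist(lapply(net$segments, function(s) rep(s$radius_mm, nrow(s$centerline_mm))))
  writeLines(c(paste("POINT_DATA", nrow(pts)),
               "SCALARS radius_mm float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(rad, trim = TRUE), con)
  invisible(path)
}
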