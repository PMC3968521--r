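# Territory triple used for distribution accounting (MCAs pooled; basilar
# branches pooled with the PCAs as the posterior group).
#' @noRd
outlet_territory_map <- function(net) {
  outlets <- nodes_of_kind(net, "outlet")
  vapply(setNames(outlets, outlets), function(nid) {
    seg <- Filter(function(s) s$proximal == nid || s$distal == nid, net$segments)[[1]]
    switch(seg$territory,
           MCA_R = , MCA_L = "MCA",
           ACA = "ACA",
           POSTERIOR = "BA_PCA",
           seg$territory)
  }, "")
}

#' @noRd
outlet_side_map <- function(net) {
  outlets <- nodes_of_kind(net, "outlet")
  vapply(setNames(outlets, outlets), function(nid) {
    if (startsWith(nid, "R_")) "right"
    else if (startsWith(nid, "L_")) "left"
    else "midline"
  }, "")
}

#' Average travel speed of an exited particle (m/s)
#'
#' Path length divided by residence time, i.e. the mean speed along the
#' particle's true path.
#'
#' @param record a `trajectory_record`.
#' @export
average_speed <- function(record) {
  if (record$status != "exited")
    stop("average speed is defined for exited particles only", call. = FALSE)
  record$path_m / record$residence_s
}

#' Exit distribution over outlets, territories or sides
#'
#' Percentages are computed over exited particles; trapped and deposited
#' particles are reported separately and excluded from the 100% base.
#'
#' @param records a `trajectory_set`.
#' @param grouping `"outlet"`, `"territory"` (ACA / MCA / BA_PCA) or `"side"`
#'   (side of the exit outlet: left / right / midline).
#' @param net the network the records were tracked on (needed for territory
#'   and side grouping).
#' @return an object of class `exit_distribution`: list with `grouping`,
#'   `percentages` (named, summing to 100 over exited particles), `n_exited`,
#'   `n_trapped`, `n_deposited` and `empty` (TRUE when nothing exited).
#' @export
exit_distribution <- function(records, grouping = c("outlet", "territory", "side"),
                              net = NULL) {
  grouping <- match.arg(grouping)
  status <- vapply(records, `[[`, "", "status")
  exited <- records[status == "exited"]
  out <- list(grouping = grouping,
              n_exited = length(exited),
              n_trapped = sum(status == "trapped"),
              n_deposited = sum(status == "deposited"))
  if (!length(exited)) {
    out$percentages <- setNames(numeric(0), character(0))
    out$empty <- TRUE
    return(structure(out, class = "exit_distribution"))
  }
  outlets <- vapply(exited, `[[`, "", "outlet")
  key <- switch(grouping,
    outlet = outlets,
    territory = {
      if (is.null(net)) stop("territory grouping needs the network", call. = FALSE)
      outlet_territory_map(net)[outlets]
    },
    side = {
      if (is.null(net)) stop("side grouping needs the network", call. = FALSE)
      outlet_side_map(net)[outlets]
    })
  tab <- table(key)
  out$percentages <- setNames(100 * as.numeric(tab) / length(exited), names(tab))
  out$empty <- FALSE
  structure(out, class = "exit_distribution")
}

#' @export
print.exit_distribution <- function(x, ...) {
  cat("<exit_distribution> by ", x$grouping, " (", x$n_exited, " exited, ",
      x$n_trapped, " trapped, ", x$n_deposited, " deposited)\n", sep = "")
  if (!x$empty)
    print(round(x$percentages, 2))
  invisible(x)
}

#' @noRd
make_histogram <- function(values, width, origin = 0) {
  if (width <= 0) stop("bin width must be > 0", call. = FALSE)
  if (!length(values)) stop("no samples to histogram", call. = FALSE)
  lo <- floor((min(values) - origin) / width)
  hi <- ceiling((max(values) - origin) / width)
  if (hi * width + origin <= max(values)) hi <- hi + 1
  edges <- origin + width * seq.int(lo, hi)
  # half-open [a, b) bins, upper-inclusive last bin
  idx <- pmin(findInterval(values, edges, left.open = FALSE), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, frequencies = counts / length(values),
                 n = length(values)),
            class = "speed_time_histogram")
}

#' Histogram of average travel speeds of exited particles
#'
#' Normalized frequencies over half-open bins (the last bin is
#' upper-inclusive); a boundary sample lands in the upper bin.
#'
#' @param records a `trajectory_set`.
#' @param width bin width in m/s (default 0.025).
#' @return list with `edges`, `frequencies` (summing to 1) and `n`.
#' @export
speed_histogram <- function(records, width = 0.025) {
  ex <- records[vapply(records, `[[`, "", "status") == "exited"]
  if (!length(ex)) stop("no exited particles to histogram", call. = FALSE)
  make_histogram(vapply(ex, average_speed, 0), width)
}

#' Histogram of residence times of exited particles
#'
#' @param records a `trajectory_set`.
#' @param width bin width in s (default 0.1).
#' @export
time_histogram <- function(records, width = 0.1) {
  ex <- records[vapply(records, `[[`, "", "status") == "exited"]
  if (!length(ex)) stop("no exited particles to histogram", call. = FALSE)
  make_histogram(vapply(ex, `[[`, 0, "residence_s"), width)
}

#' Particle path tortuosity (percent)
#'
#' `100 (path length - route length) / route length`, with the route length
#' the shortest centerline distance from the release inlet to the exit outlet
#' (see [route_length()]). Zero for a particle that travels exactly on the
#' centerline; slightly negative values are possible when a particle cuts a
#' bend inside the lumen, and are reported as computed.
#'
#' @param record an exited `trajectory_record`.
#' @param route_length_mm centerline route length in mm.
#' @export
tortuosity <- function(record, route_length_mm) {
  if (record$status != "exited")
    stop("tortuosity is defined for exited particles only", call. = FALSE)
  if (!is.numeric(route_length_mm) || route_length_mm <= 0)
    stop("route length must be > 0", call. = FALSE)
  100 * (record$path_m / MM - route_length_mm) / route_length_mm
}

#' Assemble the per-case outcome tables
#'
#' Aggregates one or more trajectory sets into the standard report tables:
#' per-case mean travel speed and residence time, exit distributions by
#' territory per release mode and inlet, and per-route mean tortuosity.
#'
#' @param record_sets list of `trajectory_set` objects (one per case x release
#'   mode), or a single set.
#' @param net the network the records were tracked on.
#' @return list of data frames: `case_stats`, `exit_by_territory`,
#'   `exit_by_outlet`, `tortuosity_by_route`.
#' @export
case_report <- function(record_sets, net) {
  if (inherits(record_sets, "trajectory_set")) record_sets <- list(record_sets)
  sum_df <- do.call(rbind, lapply(record_sets, summarize_records))
  groups <- split(sum_df, list(sum_df$case, sum_df$release_mode), drop = TRUE)
  case_stats <- do.call(rbind, lapply(groups, function(g) {
    ex <- g[g$status == "exited", ]
    data.frame(case = g$case[1], release_mode = g$release_mode[1],
               n_released = nrow(g), n_exited = nrow(ex),
               n_trapped = sum(g$status == "trapped"),
               n_deposited = sum(g$status == "deposited"),
               mean_speed_m_s = if (nrow(ex)) mean(ex$avg_speed_m_s) else NA_real_,
               mean_residence_s = if (nrow(ex)) mean(ex$residence_s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(case_stats) <- NULL

  exit_terr <- do.call(rbind, lapply(record_sets, function(rs) {
    sdf <- summarize_records(rs)
    do.call(rbind, lapply(split(sdf, sdf$release_inlet), function(g) {
      ex <- g[g$status == "exited", ]
      terr <- outlet_territory_map(net)
      pct <- function(tt) if (nrow(ex)) 100 * sum(terr[ex$outlet] == tt) / nrow(ex) else NA_real_
      data.frame(case = g$case[1], release_mode = g$release_mode[1],
                 release_inlet = g$release_inlet[1], n_exited = nrow(ex),
                 ACA = pct("ACA"), MCA = pct("MCA"), BA_PCA = pct("BA_PCA"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(exit_terr) <- NULL

  exit_out <- do.call(rbind, lapply(record_sets, function(rs) {
    d <- exit_distribution(rs, "outlet")
    if (d$empty) return(NULL)
    data.frame(case = attr(rs, "case"), release_mode = attr(rs, "mode"),
               outlet = names(d$percentages),
               percent = as.numeric(d$percentages), stringsAsFactors = FALSE)
  }))
  if (!is.null(exit_out)) rownames(exit_out) <- NULL

  tort <- do.call(rbind, lapply(record_sets, function(rs) {
    ex <- rs[vapply(rs, `[[`, "", "status") == "exited"]
    if (!length(ex)) return(NULL)
    df <- data.frame(
      case = vapply(ex, function(r) r$case %||% NA_character_, ""),
      release_mode = vapply(ex, `[[`, "", "release_mode"),
      inlet = vapply(ex, `[[`, "", "release_inlet"),
      outlet = vapply(ex, `[[`, "", "outlet"),
      stringsAsFactors = FALSE)
    df$tortuosity_pct <- vapply(seq_len(nrow(df)), function(i)
      tortuosity(ex[[i]], route_length(net, df$inlet[i], df$outlet[i])), 0)
    agg <- aggregate(tortuosity_pct ~ case + release_mode + inlet + outlet,
                     df, mean)
    agg$n <- aggregate(tortuosity_pct ~ case + release_mode + inlet + outlet,
                       df, length)$tortuosity_pct
    agg
  }))
  if (!is.null(tort)) rownames(tort) <- NULL

  list(case_stats = case_stats, exit_by_territory = exit_terr,
       exit_by_outlet = exit_out, tortuosity_by_route = tort)
}
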