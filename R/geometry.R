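#' Length of a 3-D polyline
#'
#' Sum of consecutive chord lengths of an ordered set of points.
#'
#' @param pts numeric matrix with one point per row and columns x, y, z.
#' @return total length in the unit of `pts`.
#' @export
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

#' @noRd
as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("a point must be three finite coordinates (x, y, z)", call. = FALSE)
  p
}

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic orthonormal basis (e1, e2) of the plane perpendicular to t.
#' @noRd
plane_basis <- function(t) {
  t <- unit(t)
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(cross3(ref, t))
  e2 <- cross3(t, e1)
  list(e1 = e1, e2 = e2)
}
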