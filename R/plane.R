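#' Construct a plane
#'
#' A plane is stored as an origin point and a unit normal, both in world mm.
#'
#' @param origin Length-3 point on the plane (mm, LPS).
#' @param normal Length-3 normal vector; normalized on construction.
#' @return Object of class `plane` with fields `origin` and `normal`
#'   (`||normal|| = 1`).
#' @export
plane <- function(origin, normal) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  stopifnot(length(origin) == 3, length(normal) == 3,
            all(is.finite(origin)), all(is.finite(normal)))
  structure(list(origin = origin, normal = unitize(normal)), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> origin (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Plane through three points
#'
#' @param p1,p2,p3 Length-3 points (mm). Must not be collinear.
#' @param min_area Minimum triangle area (mm^2) below which the points are
#'   rejected as (near-)collinear.
#' @return A [plane()] with origin at the centroid of the three points.
#' @export
plane_from_points <- function(p1, p2, p3, min_area = 1) {
  n <- cross3(p2 - p1, p3 - p1)
  if (0.5 * vnorm(n) < min_area) {
    stop("degenerate plane: the three points are collinear or nearly so ",
         sprintf("(triangle area %.4g mm^2 < %g mm^2)", 0.5 * vnorm(n), min_area),
         call. = FALSE)
  }
  plane((p1 + p2 + p3) / 3, n)
}

#' Signed distance from points to a plane
#'
#' Positive on the side the normal points to.
#'
#' @param pl A [plane()].
#' @param points n x 3 matrix or length-3 vector.
#' @return Numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(pl, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  as.numeric(sweep(points, 2, pl$origin) %*% pl$normal)
}

#' Orthogonal projection of points onto a plane
#'
#' @inheritParams plane_signed_distance
#' @return n x 3 matrix of projected points (or length-3 vector for a single
#'   point input).
#' @export
plane_project <- function(pl, points) {
  single <- is.null(dim(points))
  if (single) points <- matrix(points, 1)
  d <- plane_signed_distance(pl, points)
  res <- points - outer(d, pl$normal)
  if (single) as.numeric(res) else res
}

#' Orthonormal in-plane basis
#'
#' Returns unit vectors `u`, `v` such that (u, v, normal) is right-handed.
#' By default `u` is the normalized projection of world +x onto the plane
#' (+y when the normal is nearly parallel to +x); a `reference` direction may
#' be supplied instead, in which case `u` is its in-plane projection. An
#' anatomically anchored reference keeps in-plane angles equivariant under
#' rigid motion of the whole scene.
#'
#' @param pl A [plane()].
#' @param reference Optional length-3 direction whose in-plane projection
#'   defines `u`.
#' @return List with unit vectors `u` and `v`.
#' @export
plane_basis <- function(pl, reference = NULL) {
  n <- pl$normal
  if (is.null(reference)) {
    reference <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  }
  u <- reference - sum(reference * n) * n
  if (vnorm(u) < 1e-9) {
    reference <- if (abs(n[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
    u <- reference - sum(reference * n) * n
  }
  u <- unitize(u)
  list(u = u, v = cross3(n, u))
}

# World -> in-plane 2D coordinates (relative to the plane origin).
plane_to_2d <- function(pl, points, basis = plane_basis(pl)) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  rel <- sweep(points, 2, pl$origin)
  cbind(as.numeric(rel %*% basis$u), as.numeric(rel %*% basis$v))
}

# In-plane 2D -> world coordinates.
plane_from_2d <- function(pl, xy, basis = plane_basis(pl)) {
  if (is.null(dim(xy))) xy <- matrix(xy, 1)
  sweep(outer(xy[, 1], basis$u) + outer(xy[, 2], basis$v), 2, pl$origin, "+")
}
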