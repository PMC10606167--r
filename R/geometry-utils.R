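# Low-level 3D/2D geometry helpers shared across modules. All coordinates are
# millimetres in the LPS world frame; points are rows of n x 3 matrices.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

#' Random rigid transform
#'
#' Draws a uniform random rotation (via QR of a Gaussian matrix, sign-fixed
#' to a proper rotation) and a translation with components in
#' `[-t_max, t_max]`. Used for equivariance checks.
#'
#' @param t_max Maximum absolute translation per axis (mm).
#' @return List with `R` (3x3 rotation) and `t` (length-3 translation, mm).
#' @export
random_rigid_transform <- function(t_max = 50) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  R <- qr.Q(qr_d)
  R <- R %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::runif(3, -t_max, t_max))
}

#' Apply a rigid transform to points
#'
#' @param x n x 3 matrix of points (or a length-3 vector).
#' @param transform List with rotation `R` and translation `t` as returned by
#'   [random_rigid_transform()].
#' @return Transformed points, same shape as `x`.
#' @export
apply_rigid <- function(x, transform) {
  if (is.null(dim(x))) {
    as.numeric(transform$R %*% x + transform$t)
  } else {
    sweep(x %*% t(transform$R), 2, transform$t, "+")
  }
}

# Signed area of a closed 2D polygon (shoelace); positive when counter-clockwise.
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_perimeter <- function(xy) {
  d <- xy - xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Area centroid of a simple closed 2D polygon.
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Even-odd point-in-polygon test for a single 2D point.
point_in_polygon <- function(p, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > p[2]) != (yn > p[2]))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (p[2] - y[crosses]) / (yn[crosses] - y[crosses]) *
    (xn[crosses] - x[crosses])
  sum(xi > p[1]) %% 2 == 1
}

#' Test whether points lie inside a closed surface mesh
#'
#' Ray-casting parity test: a point is inside when a ray cast along a fixed
#' direction crosses the surface an odd number of times. The ray direction is
#' chosen pseudo-deterministically and re-drawn on the rare degenerate hit of
#' an edge or vertex.
#'
#' @param mesh A `surface_mesh`.
#' @param points n x 3 matrix of query points (mm).
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  dirs <- rbind(c(0.28108, 0.52973, 0.80020),
                c(0.80251, 0.13007, 0.58231),
                c(0.11043, 0.90040, 0.42080))
  out <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    for (k in 1:3) {
      d <- dirs[k, ]
      # Moller-Trumbore, vectorized over triangles
      h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                 d[3] * e2[, 1] - d[1] * e2[, 3],
                 d[1] * e2[, 2] - d[2] * e2[, 1])
      det_t <- rowSums(e1 * h)
      ok <- abs(det_t) > 1e-12
      s <- sweep(a, 2, p, function(x, y) y - x)   # p - a
      u <- rowSums(s * h) / det_t
      q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
                 s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
                 s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
      vv <- (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / det_t
      tt <- rowSums(e2 * q) / det_t
      hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0
      # degenerate: hit close to a triangle border -> retry with another ray
      border <- hit & (u < 1e-9 | vv < 1e-9 | (1 - u - vv) < 1e-9)
      if (!any(border)) { out[i] <- sum(hit) %% 2 == 1; break }
      if (k == 3) out[i] <- sum(hit) %% 2 == 1
    }
  }
  out
}
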