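#' Construct a centerline
#'
#' An ordered polyline through the lumen, parameterized by cumulative arc
#' length starting at 0 at the left-ventricular end.
#'
#' @param points n x 3 matrix of ordered points (mm).
#' @return Object of class `centerline` with fields `points` and `arclength`
#'   (strictly increasing, `arclength[1] == 0`).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2, all(is.finite(points)))
  dimnames(points) <- NULL
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2) stop("degenerate centerline: all points coincide", call. = FALSE)
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  }
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

centerline_length <- function(cl) max(cl$arclength)

# Point at arc length s (linear interpolation along the polyline).
centerline_point_at <- function(cl, s) {
  s <- pmin(pmax(s, 0), centerline_length(cl))
  cbind(stats::approx(cl$arclength, cl$points[, 1], xout = s)$y,
        stats::approx(cl$arclength, cl$points[, 2], xout = s)$y,
        stats::approx(cl$arclength, cl$points[, 3], xout = s)$y)
}

#' Resample a centerline at even arc-length spacing
#'
#' The number of segments is `round(length / spacing)` (at least 1), so both
#' endpoints are preserved exactly and the realized spacing differs from the
#' request by at most half a segment fraction; total length is preserved
#' within one spacing.
#'
#' @param cl A [centerline()].
#' @param spacing Target spacing (mm), > 0.
#' @return A resampled [centerline()].
#' @export
resample_centerline <- function(cl, spacing) {
  stopifnot(spacing > 0)
  L <- centerline_length(cl)
  if (L < spacing) {
    stop("centerline length ", sprintf("%.3f", L),
         " mm is shorter than the requested spacing ", spacing, " mm", call. = FALSE)
  }
  nseg <- max(1L, round(L / spacing))
  s <- seq(0, L, length.out = nseg + 1)
  centerline(centerline_point_at(cl, s))
}

#' Unit tangent of a centerline at an arc length
#'
#' Central differences on the polyline vertices, linearly interpolated
#' between vertices and normalized, giving a tangent continuous in `s`.
#'
#' @param cl A [centerline()].
#' @param s Arc length(s) in `[0, length]` (mm).
#' @return Unit 3-vector, or an n x 3 matrix for vector `s`.
#' @export
tangent_at <- function(cl, s) {
  L <- centerline_length(cl)
  if (any(s < -1e-9 | s > L + 1e-9)) {
    stop("arc length out of range [0, ", sprintf("%.3f", L), "]", call. = FALSE)
  }
  s <- pmin(pmax(s, 0), L)
  p <- cl$points
  n <- nrow(p)
  # per-vertex central-difference tangents
  vt <- rbind(p[2, ] - p[1, ],
              p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
              p[n, ] - p[n - 1, ])
  vt <- vt / sqrt(rowSums(vt^2))
  tx <- stats::approx(cl$arclength, vt[, 1], xout = s)$y
  ty <- stats::approx(cl$arclength, vt[, 2], xout = s)$y
  tz <- stats::approx(cl$arclength, vt[, 3], xout = s)$y
  out <- cbind(tx, ty, tz)
  out <- out / sqrt(rowSums(out^2))
  if (length(s) == 1) as.numeric(out) else out
}

#' Transform a centerline rigidly
#'
#' @param cl A [centerline()].
#' @param transform List with `R` and `t`.
#' @return Transformed `centerline`.
#' @export
transform_centerline <- function(cl, transform) {
  centerline(apply_rigid(cl$points, transform))
}

#' Extract a centerline by cross-section centroid marching
#'
#' Fallback/cross-check extractor: starting from a seed plane, the mesh is
#' sliced, the plane is re-centered on the cross-section centroid, and after
#' the first two stations the marching direction follows the last two
#' centroids. Marching proceeds in both directions from the seed and stops
#' cleanly when the section vanishes or degenerates (the plane exits the
#' mesh).
#'
#' @param mesh A [surface_mesh()].
#' @param seed_plane A [plane()] intersecting the mesh; its origin must be
#'   inside the lumen.
#' @param step Plane advance per station (mm), default 1.
#' @param max_steps Per-direction station cap (divergence guard).
#' @return A [centerline()] ordered along the seed normal direction.
#' @export
extract_centerline_marching <- function(mesh, seed_plane, step = 1,
                                        max_steps = 500) {
  march <- function(origin, normal) {
    pts <- list()
    prev <- NULL
    prev_area <- NULL
    for (k in seq_len(max_steps)) {
      sec <- tryCatch(slice_mesh(mesh, plane(origin, normal), anchor = origin),
                      error = function(e) NULL)
      if (is.null(sec)) break
      cen <- sec$centroid
      if (!is.null(prev)) {
        disp <- vnorm(cen - prev)
        # centroid jump or area collapse: the plane grazed an end cap or left
        # the lumen -> terminate this direction cleanly
        if (disp > 2 * step || sec$area < 0.4 * prev_area) break
        dir <- cen - prev
        if (sum(dir * normal) < 0) {
          stop("marching divergence: centroid track reversed at step ", k,
               call. = FALSE)
        }
        if (vnorm(dir) > 1e-9) normal <- unitize(dir)
      }
      pts[[length(pts) + 1]] <- cen
      prev <- cen
      prev_area <- sec$area
      origin <- cen + step * normal
    }
    pts
  }
  n0 <- seed_plane$normal
  fwd <- march(seed_plane$origin, n0)
  bwd <- march(seed_plane$origin, -n0)
  if (length(fwd) + length(bwd) < 2) {
    stop("marching failed: seed plane does not intersect the mesh in a usable loop",
         call. = FALSE)
  }
  pts <- do.call(rbind, c(rev(bwd), fwd))
  # the seed station appears once per direction; drop the duplicate
  if (length(bwd) >= 1 && length(fwd) >= 1) {
    pts <- pts[-length(bwd), , drop = FALSE]
  }
  centerline(pts)
}
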