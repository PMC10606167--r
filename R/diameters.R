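# Centroid-chord diameters. A chord at angle theta is the full line through
# the section centroid; its endpoints are the farthest boundary crossings on
# each side, so non-convex contours still yield the outer-to-outer distance.

# Chord lengths of the line through p0 at each angle (degrees, in-plane).
# Returns a numeric vector (NA where the line misses the contour on a side).
# Vectorized over angles in memory-bounded blocks.
chord_scan <- function(xy, p0, angles_deg, block = 2000L) {
  n <- nrow(xy)
  rel <- sweep(xy, 2, p0)                         # points relative to p0
  nxt <- c(2:n, 1L)
  out <- rep(NA_real_, length(angles_deg))
  for (b0 in seq(1L, length(angles_deg), by = block)) {
    idx <- b0:min(b0 + block - 1L, length(angles_deg))
    th <- angles_deg[idx] * pi / 180
    U <- rbind(cos(th), sin(th))                  # 2 x m line directions
    W <- rbind(-sin(th), cos(th))                 # 2 x m line normals
    S <- rel %*% W                                # n x m signed dists to line
    Tm <- rel %*% U                               # n x m along-line coords
    S1 <- S; S2 <- S[nxt, , drop = FALSE]
    T1 <- Tm; T2 <- Tm[nxt, , drop = FALSE]
    crossing <- (S1 > 0) != (S2 > 0)
    tcross <- (T1 * S2 - T2 * S1) / (S2 - S1)     # valid where crossing
    tcross[!crossing] <- NA_real_
    tpos <- tcross; tpos[!is.na(tpos) & tpos <= 0] <- NA_real_
    tneg <- tcross; tneg[!is.na(tneg) & tneg >= 0] <- NA_real_
    suppressWarnings({
      hi <- apply(tpos, 2, max, na.rm = TRUE)
      lo <- apply(tneg, 2, min, na.rm = TRUE)
    })
    val <- is.finite(hi) & is.finite(lo)
    out[idx[val]] <- hi[val] - lo[val]
  }
  out
}

# Endpoints (2D) of the chord through p0 along unit direction u2d, taking the
# two crossings farthest apart on opposite sides; NULL when a side is missed.
chord_through <- function(xy, p0, u2d) {
  len <- chord_scan(xy, p0, atan2(u2d[2], u2d[1]) * 180 / pi)
  if (is.na(len)) return(NULL)
  # recompute extreme parameters for the endpoints
  n <- nrow(xy)
  rel <- sweep(xy, 2, p0)
  w <- c(-u2d[2], u2d[1])
  s <- as.numeric(rel %*% w)
  tt <- as.numeric(rel %*% u2d)
  nxt <- c(2:n, 1L)
  crossing <- (s > 0) != (s[nxt] > 0)
  tc <- (tt[crossing] * s[nxt][crossing] - tt[nxt][crossing] * s[crossing]) /
    (s[nxt][crossing] - s[crossing])
  hi <- max(tc[tc > 0]); lo <- min(tc[tc < 0])
  list(p_lo = p0 + lo * u2d, p_hi = p0 + hi * u2d, length = hi - lo,
       n_crossings = length(tc))
}

#' Minimum and maximum centroid-chord diameters
#'
#' Scans directions theta in `[0, 180)` degrees at `angular_step`; for each,
#' the chord through the section centroid is intersected with the contour on
#' both sides and its length recorded. `d_min`/`d_max` are the extreme chord
#' lengths; ties break toward the smaller angle. Directions where the chord
#' misses the contour on one side (non-star-shaped contours) are skipped.
#'
#' @param section A `cross_section` from [slice_mesh()].
#' @param angular_step Angular resolution in degrees (0 < step <= 1;
#'   default 0.5).
#' @return List with `d_min`, `d_max` (mm), `theta_min`, `theta_max`
#'   (degrees relative to the in-plane basis), and `n_skipped`.
#' @export
min_max_diameters <- function(section, angular_step = 0.5) {
  stopifnot(angular_step > 0, angular_step <= 1)
  angles <- seq(0, 180 - angular_step / 2, by = angular_step)
  len <- chord_scan(section$contour2d, section$centroid2d, angles)
  ok <- !is.na(len)
  if (!any(ok)) {
    stop("geometry error: no centroid chord intersects the contour on both sides",
         call. = FALSE)
  }
  imin <- which(len == min(len[ok]))[1]
  imax <- which(len == max(len[ok]))[1]
  list(d_min = len[imin], d_max = len[imax],
       theta_min = angles[imin], theta_max = angles[imax],
       n_skipped = sum(!ok))
}

#' Area- and perimeter-derived diameters
#'
#' The diameter of the circle with the section's area, `2*sqrt(area/pi)`, and
#' of the circle with its perimeter, `perimeter/pi`. By the isoperimetric
#' inequality `d_perim >= d_area`, with equality only for a circle.
#'
#' @param area Cross-section area (mm^2), positive.
#' @param perimeter Cross-section perimeter (mm), positive.
#' @return List with `d_area` and `d_perim` (mm).
#' @export
derived_diameters <- function(area, perimeter) {
  if (!is.finite(area) || !is.finite(perimeter) || area <= 0 || perimeter <= 0) {
    stop("derived diameters require positive finite area and perimeter", call. = FALSE)
  }
  list(d_area = 2 * sqrt(area / pi), d_perim = perimeter / pi)
}

# The 7 per-section metrics used for the annulus and LVOT report rows.
section_metrics <- function(section, angular_step = 0.5) {
  mm <- min_max_diameters(section, angular_step)
  dd <- derived_diameters(section$area, section$perimeter)
  c(area = section$area, perimeter = section$perimeter,
    diameter_min = mm$d_min, diameter_max = mm$d_max,
    diameter_avg = (mm$d_min + mm$d_max) / 2,
    diameter_area_derived = dd$d_area,
    diameter_perimeter_derived = dd$d_perim)
}
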