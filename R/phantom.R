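# Parametric synthetic aortic-root + LV phantom. The surface is a tube swept
# along a straight or circular-arc centerline with radius profile
#   r(s, phi) = base(s) + sum_i bulge(s) * amp_i * lobe_i(phi)
# where base(s) runs piecewise-smoothly through r_lvot -> r_annulus ->
# r_stj -> r_aorta and each sinus adds a raised-cosine axial bulge times a
# raised-cosine angular lobe of 120 deg support centered on its nadir
# azimuth. Because the axial bulge has compact support starting above the
# annulus and ending at the sinotubular junction, the annulus section is an
# exact circle of radius r_annulus and the area profile is exactly constant
# above the junction, giving clean analytic ground truth.

#' Specify a synthetic aortic-root phantom
#'
#' All lengths in mm, azimuths in degrees. Defaults describe a typical TAVI
#' anatomy: 25 mm annulus diameter, 34 mm sinus diameter, sinus bulge peaking
#' 10 mm above the annulus, coronary ostia 14 mm (left) and 12 mm (right)
#' above the annulus.
#'
#' @param r_lvot LVOT tube radius.
#' @param r_annulus Annulus radius.
#' @param r_sinus_lcc,r_sinus_rcc,r_sinus_ncc Peak total radius of each sinus
#'   at the bulge center.
#' @param bulge_center Height of the sinus bulge center above the annulus.
#' @param bulge_width Axial full width of the raised-cosine bulge; its
#'   support is `bulge_center +/- bulge_width/2` and must lie within
#'   `(0, l_sinus]`.
#' @param r_stj Base radius at the top of the sinus region.
#' @param r_aorta Ascending-aorta radius (equal to `r_stj` by default so the
#'   area profile stabilizes exactly at the end of the bulge).
#' @param l_lv,l_sinus,l_aorta Segment lengths: LV end to annulus, annulus to
#'   sinotubular junction, junction to the aortic end.
#' @param taper_below,taper_above Axial lengths of the smooth base-radius
#'   blends ending at the annulus (from `r_lvot`) and starting at it
#'   (to `r_stj`).
#' @param lch,rch Ostium heights above the annulus (arc length along the
#'   centerline).
#' @param ostium_azimuth_left,ostium_azimuth_right Ostium azimuths (deg).
#' @param nadir_azimuths Azimuths (deg) of the LC, RC, NC nadirs; also the
#'   sinus lobe centers.
#' @param curvature_radius Radius of the circular-arc centerline
#'   (`Inf` = straight).
#' @param n_circ,axial_spacing Mesh resolution: circumferential vertex count
#'   and axial ring spacing.
#' @param noise Amplitude of uniform radial surface noise.
#' @param seed RNG seed for the noise (ignored when `noise = 0`).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(r_lvot = 11, r_annulus = 12.5,
                         r_sinus_lcc = 17, r_sinus_rcc = 17, r_sinus_ncc = 17,
                         bulge_center = 10, bulge_width = 16,
                         r_stj = 14, r_aorta = r_stj,
                         l_lv = 50, l_sinus = 18, l_aorta = 22,
                         taper_below = 6, taper_above = 6,
                         lch = 14, rch = 12,
                         ostium_azimuth_left = 90, ostium_azimuth_right = 210,
                         nadir_azimuths = c(lc = 90, rc = 210, nc = 330),
                         curvature_radius = Inf,
                         n_circ = 64, axial_spacing = 0.8,
                         noise = 0, seed = 1) {
  spec <- as.list(environment())
  radii <- c(r_lvot, r_annulus, r_sinus_lcc, r_sinus_rcc, r_sinus_ncc, r_stj, r_aorta)
  if (any(radii <= 0) || any(c(l_lv, l_sinus, l_aorta) <= 0)) {
    stop("phantom spec error: radii and segment lengths must be positive", call. = FALSE)
  }
  if (bulge_center - bulge_width / 2 < 0 || bulge_center + bulge_width / 2 > l_sinus + 1e-9) {
    stop("phantom spec error: bulge support [",
         bulge_center - bulge_width / 2, ", ", bulge_center + bulge_width / 2,
         "] must lie within (0, l_sinus = ", l_sinus, "]", call. = FALSE)
  }
  if (any(c(lch, rch) >= l_sinus + l_aorta)) {
    stop("phantom spec error: ostium heights must be below the aortic end", call. = FALSE)
  }
  if (noise < 0 || noise >= 0.2 * min(radii)) {
    stop("phantom spec error: noise amplitude must be in [0, 0.2 * min radius)",
         call. = FALSE)
  }
  if (is.finite(curvature_radius) &&
      curvature_radius < 2 * max(radii)) {
    stop("phantom spec error: curvature radius ", curvature_radius,
         " mm too small for tube radius (self-intersection)", call. = FALSE)
  }
  if (min(r_sinus_lcc, r_sinus_rcc, r_sinus_ncc) <= r_stj) {
    stop("phantom spec error: sinus peak radii must exceed r_stj", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> annulus r %.1f mm, sinus peaks %.1f/%.1f/%.1f mm, %s axis\n",
              x$r_annulus, x$r_sinus_lcc, x$r_sinus_rcc, x$r_sinus_ncc,
              if (is.finite(x$curvature_radius)) sprintf("curved (R=%g mm)", x$curvature_radius) else "straight"))
  invisible(x)
}

phantom_total_length <- function(spec) spec$l_lv + spec$l_sinus + spec$l_aorta

# Base radius profile as a function of arc length s (vectorized).
phantom_base_radius <- function(spec, s) {
  sa <- spec$l_lv
  r <- rep(spec$r_lvot, length(s))
  # blend r_lvot -> r_annulus over [sa - taper_below, sa] (raised cosine)
  i <- s > sa - spec$taper_below & s <= sa
  x <- (s[i] - (sa - spec$taper_below)) / spec$taper_below
  r[i] <- spec$r_lvot + (spec$r_annulus - spec$r_lvot) * (0.5 - 0.5 * cos(pi * x))
  # blend r_annulus -> r_stj over [sa, sa + taper_above]
  i <- s > sa & s <= sa + spec$taper_above
  x <- (s[i] - sa) / spec$taper_above
  r[i] <- spec$r_annulus + (spec$r_stj - spec$r_annulus) * (0.5 - 0.5 * cos(pi * x))
  i <- s > sa + spec$taper_above & s <= sa + spec$l_sinus
  r[i] <- spec$r_stj
  # blend r_stj -> r_aorta over 4 mm above the junction (no-op when equal)
  blend_len <- 4
  i <- s > sa + spec$l_sinus
  x <- pmin((s[i] - (sa + spec$l_sinus)) / blend_len, 1)
  r[i] <- spec$r_stj + (spec$r_aorta - spec$r_stj) * (0.5 - 0.5 * cos(pi * x))
  r
}

# Axial bulge shape (raised cosine, support bulge_center +/- width/2 above
# the annulus), normalized to 1 at the center.
phantom_bulge_axial <- function(spec, s) {
  h <- s - spec$l_lv - spec$bulge_center
  w <- spec$bulge_width
  out <- numeric(length(s))
  i <- abs(h) < w / 2
  out[i] <- 0.5 + 0.5 * cos(2 * pi * h[i] / w)
  out
}

# Angular lobes: raised cosine of 120 deg support centered on each nadir
# azimuth, normalized to 1 at the center. Returns an n x 3 matrix (LC,RC,NC).
phantom_lobes <- function(spec, phi_deg) {
  out <- matrix(0, length(phi_deg), 3)
  centers <- spec$nadir_azimuths
  for (k in 1:3) {
    d <- ((phi_deg - centers[k] + 180) %% 360) - 180
    i <- abs(d) < 60
    out[i, k] <- 0.5 + 0.5 * cos(3 * d[i] * pi / 180)
  }
  out
}

# Total radius r(s, phi) (s and phi_deg vectors of equal length, or one of
# them scalar).
phantom_radius <- function(spec, s, phi_deg) {
  n <- max(length(s), length(phi_deg))
  s <- rep_len(s, n); phi_deg <- rep_len(phi_deg, n)
  base <- phantom_base_radius(spec, s)
  bs <- phantom_bulge_axial(spec, s)
  amps <- c(spec$r_sinus_lcc, spec$r_sinus_rcc, spec$r_sinus_ncc) - spec$r_stj
  lob <- phantom_lobes(spec, phi_deg)
  base + bs * as.numeric(lob %*% amps)
}

# Sweep frame: centerline point C(s), tangent T(s), and in-plane axes
# N(s), B(s) with phi measured from N toward B. Straight axis is +z.
phantom_frame <- function(spec, s) {
  R <- spec$curvature_radius
  if (!is.finite(R)) {
    n <- length(s)
    list(C = cbind(0, 0, s),
         T = matrix(rep(c(0, 0, 1), each = n), n),
         N = matrix(rep(c(1, 0, 0), each = n), n),
         B = matrix(rep(c(0, 1, 0), each = n), n))
  } else {
    a <- s / R
    list(C = cbind(R - R * cos(a), 0, R * sin(a)),
         T = cbind(sin(a), 0, cos(a)),
         N = cbind(cos(a), 0, -sin(a)),
         B = matrix(rep(c(0, 1, 0), each = length(s)), length(s)))
  }
}

phantom_surface_point <- function(spec, s, phi_deg) {
  n <- max(length(s), length(phi_deg))
  s <- rep_len(s, n); phi_deg <- rep_len(phi_deg, n)
  fr <- phantom_frame(spec, s)
  r <- phantom_radius(spec, s, phi_deg)
  phi <- phi_deg * pi / 180
  fr$C + r * (cos(phi) * fr$N + sin(phi) * fr$B)
}

#' Generate a synthetic aortic-root phantom
#'
#' Builds the closed triangulated surface, the five landmark points (placed
#' exactly on the analytic surface) and the analytic ground truth for all 22
#' measurements. Deterministic for a fixed spec (the noise RNG is seeded
#' from `spec$seed` and the global RNG state is left untouched).
#'
#' @param spec A [phantom_spec()].
#' @return List with `mesh` ([surface_mesh()]), `landmarks`
#'   ([landmark_set()]) and `truth` (see [phantom_truth()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- phantom_total_length(spec)
  nz <- ceiling(L / spec$axial_spacing)
  svals <- seq(0, L, length.out = nz + 1)
  phi <- seq(0, 360, length.out = spec$n_circ + 1)[-(spec$n_circ + 1)]
  grid_s <- rep(svals, each = spec$n_circ)
  grid_phi <- rep(phi, nz + 1)
  verts <- phantom_surface_point(spec, grid_s, grid_phi)
  if (spec$noise > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    fr <- phantom_frame(spec, grid_s)
    rphi <- grid_phi * pi / 180
    radial <- cos(rphi) * fr$N + sin(rphi) * fr$B
    verts <- verts + stats::runif(nrow(verts), -spec$noise, spec$noise) * radial
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old_seed, envir = globalenv())
  }
  nc <- spec$n_circ
  idx <- function(i, k) (i - 1L) * nc + k        # ring i, azimuth slot k
  i <- rep(seq_len(nz), each = nc)
  k <- rep(seq_len(nc), nz)
  k2 <- k %% nc + 1L
  f1 <- cbind(idx(i, k), idx(i, k2), idx(i + 1L, k))
  f2 <- cbind(idx(i + 1L, k), idx(i, k2), idx(i + 1L, k2))
  nb <- nrow(verts)
  fr_end <- phantom_frame(spec, c(0, L))
  verts <- rbind(verts, fr_end$C[1, ], fr_end$C[2, ])
  kk <- seq_len(nc); kk2 <- kk %% nc + 1L
  cap0 <- cbind(nb + 1L, idx(1L, kk2), idx(1L, kk))
  capL <- cbind(nb + 2L, idx(nz + 1L, kk), idx(nz + 1L, kk2))
  mesh <- surface_mesh(verts, rbind(f1, f2, cap0, capL))
  landmarks <- phantom_landmarks(spec)
  truth <- phantom_truth(spec)
  list(mesh = mesh, landmarks = landmarks, truth = truth)
}

# The five landmarks on the analytic (noise-free) surface.
phantom_landmarks <- function(spec) {
  sa <- spec$l_lv
  naz <- spec$nadir_azimuths
  landmark_set(
    left_coronary_ostium = as.numeric(
      phantom_surface_point(spec, sa + spec$lch, spec$ostium_azimuth_left)),
    right_coronary_ostium = as.numeric(
      phantom_surface_point(spec, sa + spec$rch, spec$ostium_azimuth_right)),
    nadir_left = as.numeric(phantom_surface_point(spec, sa, naz[1])),
    nadir_right = as.numeric(phantom_surface_point(spec, sa, naz[2])),
    nadir_noncoronary = as.numeric(phantom_surface_point(spec, sa, naz[3]))
  )
}

# Analytic cross-section area at arc length s (plane perpendicular to the
# local tangent): A = 1/2 integral r(s,phi)^2 dphi, by periodic trapezoid.
phantom_section_area <- function(spec, s, n_quad = 10000) {
  phi <- seq(0, 360, length.out = n_quad + 1)[-(n_quad + 1)]
  vapply(s, function(si) {
    r <- phantom_radius(spec, si, phi)
    sum(r^2) * (pi / n_quad)
  }, 0)
}

# Dense 2D contour of the tangent-plane section at s (local N/B coordinates).
phantom_section_contour <- function(spec, s, n = 8192) {
  phi <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  r <- phantom_radius(spec, s, phi)
  cbind(r * cos(phi * pi / 180), r * sin(phi * pi / 180))
}

#' Analytic ground truth for a phantom
#'
#' Computes the 22 measurements implied by a [phantom_spec()], using closed
#' forms where the section is an exact circle (annulus, straight-phantom
#' LVOT, sinotubular junction) and dense numerical quadrature / dense-contour
#' chord scans elsewhere (sinus-of-Valsalva section, curved-phantom LVOT).
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_truth` with the truth `report`
#'   ([measurement_report()]), the true `annulus_plane` and `lvot_plane`,
#'   arc stations `s_annulus`, `s_sov`, `s_sntj`, the true `centerline`
#'   polyline and `landmarks`.
#' @export
phantom_truth <- function(spec) {
  sa <- spec$l_lv
  L <- phantom_total_length(spec)
  fr <- phantom_frame(spec, sa)
  ann_plane <- plane(fr$C[1, ], fr$T[1, ])
  circle7 <- function(r) {
    c(area = pi * r^2, perimeter = 2 * pi * r,
      diameter_min = 2 * r, diameter_max = 2 * r, diameter_avg = 2 * r,
      diameter_area_derived = 2 * r, diameter_perimeter_derived = 2 * r)
  }
  annulus <- circle7(spec$r_annulus)
  # LVOT: plane at s_annulus - 4 with the annulus normal
  s_lvot <- sa - 4
  lv_origin <- as.numeric(phantom_frame(spec, s_lvot)$C)
  lvot_plane <- plane(lv_origin, ann_plane$normal)
  if (!is.finite(spec$curvature_radius)) {
    lvot <- circle7(phantom_base_radius(spec, s_lvot))
  } else {
    lvot <- truth_plane_section_metrics(spec, lvot_plane, s_lvot)
  }
  # SOV: bulge center (base radius is constant there by construction)
  s_sov <- sa + spec$bulge_center
  sov <- truth_sinus_diameters(spec, s_sov)
  # SNTJ: where the area profile becomes exactly constant
  s_stable_bulge <- sa + spec$bulge_center + spec$bulge_width / 2
  s_stable_base <- if (abs(spec$r_aorta - spec$r_stj) > 1e-12) sa + spec$l_sinus + 4 else -Inf
  s_sntj <- max(s_stable_bulge, s_stable_base)
  sntj <- c(diameter_min = 2 * spec$r_aorta, diameter_max = 2 * spec$r_aorta,
            diameter_avg = 2 * spec$r_aorta)
  # coronary heights: perpendicular distance of each ostium to the annulus plane
  lmk <- phantom_landmarks(spec)
  coronary <- c(
    height_left = plane_signed_distance(ann_plane, lmk$left_coronary_ostium),
    height_right = plane_signed_distance(ann_plane, lmk$right_coronary_ostium))
  names(coronary) <- c("height_left", "height_right")
  s_dense <- seq(0, L, length.out = 4 * ceiling(L) + 1)
  report <- measurement_report(
    annulus, lvot, sntj, sov$diameters, coronary,
    metadata = list(source = "phantom analytic truth", seed = spec$seed))
  structure(list(report = report,
                 annulus_plane = ann_plane,
                 lvot_plane = lvot_plane,
                 s_annulus = sa, s_sov = s_sov, s_sntj = s_sntj,
                 sov_area = phantom_section_area(spec, s_sov),
                 centerline = centerline(phantom_frame(spec, s_dense)$C),
                 landmarks = lmk, spec = spec),
            class = "phantom_truth")
}

# Metrics of the tangent-plane SOV section plus the three nadir-projection
# sinus diameters, from a dense analytic contour (the declared oracle). The
# nadirs are orthogonally projected onto the SOV plane in 3D and expressed
# in the local N/B frame, so curved phantoms are handled exactly.
truth_sinus_diameters <- function(spec, s_sov, n = 8192) {
  fr <- phantom_frame(spec, s_sov)
  pl <- plane(fr$C[1, ], fr$T[1, ])
  xy <- phantom_section_contour(spec, s_sov, n)
  cen <- polygon_centroid(xy)
  lmk <- phantom_landmarks(spec)
  nad <- nadir_matrix(lmk)
  proj <- plane_project(pl, nad)
  rel <- sweep(proj, 2, fr$C[1, ])
  p2 <- cbind(as.numeric(rel %*% fr$N[1, ]), as.numeric(rel %*% fr$B[1, ]))
  d <- numeric(3)
  for (k in 1:3) {
    u <- unitize(c(p2[k, ] - cen, 0))[1:2]
    d[k] <- chord_through(xy, cen, u)$length
  }
  list(diameters = c(diameter_lcc = d[1], diameter_rcc = d[2], diameter_ncc = d[3]),
       contour = xy, centroid = cen)
}

# Full 7-metric truth for an arbitrary plane cutting the phantom surface,
# by per-azimuth root finding of the intersection contour.
truth_plane_section_metrics <- function(spec, pl, s_hint, n = 2880,
                                        angular_step = 0.05) {
  phi <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  L <- phantom_total_length(spec)
  f <- function(s, p) sum((phantom_surface_point(spec, s, p) - pl$origin) * pl$normal)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    lo <- max(0, s_hint - 15); hi <- min(L, s_hint + 15)
    root <- stats::uniroot(f, c(lo, hi), p = phi[i], tol = 1e-10)$root
    pts[i, ] <- phantom_surface_point(spec, root, phi[i])
  }
  basis <- plane_basis(pl)
  xy <- plane_to_2d(pl, pts, basis)
  cen <- polygon_centroid(xy)
  area <- abs(polygon_signed_area(xy))
  per <- polygon_perimeter(xy)
  len <- chord_scan(xy, cen, seq(0, 180 - angular_step / 2, by = angular_step),
                    block = 500L)
  dd <- derived_diameters(area, per)
  c(area = area, perimeter = per,
    diameter_min = min(len, na.rm = TRUE), diameter_max = max(len, na.rm = TRUE),
    diameter_avg = (min(len, na.rm = TRUE) + max(len, na.rm = TRUE)) / 2,
    diameter_area_derived = dd$d_area, diameter_perimeter_derived = dd$d_perim)
}

#' Jitter a landmark set with isotropic Gaussian noise
#'
#' Used for sensitivity studies of plane orientation against landmark
#' detection error. The RNG is seeded locally; the global RNG state is
#' preserved.
#'
#' @param lm A [landmark_set()].
#' @param sigma Per-axis Gaussian standard deviation (mm), >= 0.
#' @param seed Integer seed.
#' @return A perturbed [landmark_set()].
#' @export
perturb_landmarks <- function(lm, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(lm)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- lapply(unclass(lm)[LANDMARK_NAMES],
                function(p) p + stats::rnorm(3, 0, sigma))
  if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old_seed, envir = globalenv())
  do.call(landmark_set, out)
}
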