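# Centerline extraction by Laplacian-based contraction: the mesh is
# iteratively contracted onto its medial curve by solving, at each step, the
# sparse least-squares system
#     [ W_L * L ] V' = [ 0       ]
#     [ W_H     ]      [ W_H * V ]
# where L is the cotangent Laplacian of the current geometry, W_L the
# contraction weight (doubled each iteration) and W_H per-vertex attraction
# weights that grow as the local one-ring collapses. The contracted cloud is
# then reduced to the longest geodesic path through the mesh edge graph,
# denoised by arc-length binning, interpolated with a cubic spline and
# resampled at even spacing.

# Cotangent Laplacian (sparse, symmetric, rows sum to zero) with cotangent
# clamping for near-degenerate triangles, plus per-vertex one-ring areas.
cotan_laplacian <- function(verts, faces, clamp = 60) {
  i1 <- faces[, 1]; i2 <- faces[, 2]; i3 <- faces[, 3]
  p1 <- verts[i1, , drop = FALSE]
  p2 <- verts[i2, , drop = FALSE]
  p3 <- verts[i3, , drop = FALSE]
  cot_at <- function(a, b, c) {            # cot of angle at vertex a
    u <- b - a; v <- c - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area2 <- sqrt(rowSums(cr^2))
    ct <- rowSums(u * v) / pmax(area2, 1e-12)
    pmin(pmax(ct, -clamp), clamp)
  }
  c1 <- cot_at(p1, p2, p3)                 # opposite edge (2,3)
  c2 <- cot_at(p2, p3, p1)                 # opposite edge (3,1)
  c3 <- cot_at(p3, p1, p2)                 # opposite edge (1,2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  n <- nrow(verts)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  dg <- Matrix::rowSums(W)
  L <- W - Matrix::Diagonal(n, dg)
  cr <- cbind((p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
              (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
              (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  ring <- as.numeric(Matrix::sparseMatrix(
    i = c(i1, i2, i3), j = rep(1L, 3 * nrow(faces)),
    x = rep(fa / 3, 3), dims = c(n, 1)))
  list(L = L, ring_area = ring, face_area = fa)
}

#' Default Laplacian-contraction parameters
#'
#' @param initial_laplace_weight Initial contraction weight `W_L`; when `NULL`
#'   it is set to `1 / (10 * sqrt(mean face area))`, the regime of published
#'   contraction implementations.
#' @param initial_attraction_weight Initial per-vertex attraction `W_H`.
#' @param weight_multiplier Factor applied to `W_L` each iteration.
#' @param max_weight Cap on `W_L` growth.
#' @param max_iter Iteration cap.
#' @param displacement_tol Stop when the mean vertex displacement of an
#'   iteration falls below this (mm).
#' @param area_ratio_stop Stop when total face area falls below this fraction
#'   of the original (fully contracted).
#' @param bin_width Arc-length bin width (mm) used to denoise the skeleton
#'   path before spline interpolation.
#' @param spacing Output resampling spacing (mm), <= 1 so sliding planes can
#'   be spaced at 1 mm.
#' @param refine_iterations Cross-section centroid refinement passes applied
#'   to the smoothed curve: each station is re-centered on the centroid of
#'   the mesh section perpendicular to the local tangent. Corrects the small
#'   inward bow and tangent wiggle the raw contraction skeleton carries on
#'   curved lumens; 0 disables.
#' @return Named list of parameters.
#' @export
lbc_params <- function(initial_laplace_weight = NULL,
                       initial_attraction_weight = 1,
                       weight_multiplier = 2,
                       max_weight = 2048,
                       max_iter = 20,
                       displacement_tol = 0.01,
                       area_ratio_stop = 0.01,
                       bin_width = 3,
                       spacing = 0.5,
                       refine_iterations = 2) {
  list(initial_laplace_weight = initial_laplace_weight,
       initial_attraction_weight = initial_attraction_weight,
       weight_multiplier = weight_multiplier,
       max_weight = max_weight,
       max_iter = max_iter,
       displacement_tol = displacement_tol,
       area_ratio_stop = area_ratio_stop,
       bin_width = bin_width,
       spacing = spacing,
       refine_iterations = refine_iterations)
}

# Contract mesh vertices onto the medial curve; returns contracted positions.
contract_mesh <- function(mesh, params = lbc_params()) {
  V <- mesh$vertices
  f <- mesh$faces
  n <- nrow(V)
  lap <- cotan_laplacian(V, f)
  A0 <- sum(lap$face_area)
  ring0 <- pmax(lap$ring_area, 1e-12)
  wl <- params$initial_laplace_weight
  if (is.null(wl)) wl <- 1 / (10 * sqrt(mean(lap$face_area)))
  wh <- rep(params$initial_attraction_weight, n)
  history <- numeric(0)
  ratios <- numeric(0)
  for (it in seq_len(params$max_iter)) {
    L <- lap$L
    A <- wl^2 * Matrix::crossprod(L) + Matrix::Diagonal(n, wh^2)
    b <- wh^2 * V
    Vn <- as.matrix(Matrix::solve(A, b))
    disp <- mean(sqrt(rowSums((Vn - V)^2)))
    # Once the surface has collapsed onto a curve (small area ratio) and the
    # per-iteration displacement has already passed its peak, a renewed rise
    # marks the onset of tangential curve shrinkage, which destroys the
    # skeleton's arc-length structure: keep the pre-rise geometry and stop.
    if (it >= 3 && ratios[it - 1] < 0.1 &&
        history[it - 1] < history[it - 2] && disp > history[it - 1]) {
      break
    }
    history <- c(history, disp)
    V <- Vn
    lap <- cotan_laplacian(V, f)
    ratio <- sum(lap$face_area) / A0
    ratios <- c(ratios, ratio)
    if (ratio < params$area_ratio_stop) break
    # displacement stop only counts once real contraction has happened;
    # early iterations may barely move while W_L is still small
    if (disp < params$displacement_tol && ratio < 0.5) break
    wl <- min(wl * params$weight_multiplier, params$max_weight)
    wh <- params$initial_attraction_weight *
      sqrt(ring0 / pmax(lap$ring_area, 1e-12))
  }
  area_ratio <- sum(lap$face_area) / A0
  if (area_ratio > 0.05 && history[length(history)] > params$displacement_tol) {
    stop("contraction failed to converge: after ", length(history),
         " iterations the face area ratio is ", sprintf("%.3g", area_ratio),
         " and the last mean displacement ",
         sprintf("%.3g", history[length(history)]), " mm", call. = FALSE)
  }
  list(positions = V, iterations = length(history), displacement = history,
       area_ratio = area_ratio)
}

# Longest geodesic path through the contracted cloud, using mesh edges
# weighted by contracted edge length (double Dijkstra sweep).
skeleton_path <- function(mesh, contracted) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((contracted[e[, 1], , drop = FALSE] -
                     contracted[e[, 2], , drop = FALSE])^2)) + 1e-9
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  # work on the largest component (the lumen of interest)
  main <- which(comp$membership == which.max(comp$csize))
  d1 <- igraph::distances(g, v = main[1], to = main)[1, ]
  u <- main[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = main)[1, ]
  v <- main[which.max(d2)]
  path <- igraph::shortest_paths(g, from = u, to = v, output = "vpath")$vpath[[1]]
  pts <- contracted[as.integer(path), , drop = FALSE]
  pts <- trim_end_blob(trim_end_blob(pts, 3), 3, reverse = TRUE)
  filter_backtrack(pts)
}

# Incompletely contracted regions can fold the contracted rings axially, so
# the index-ordered geodesic path locally retraces itself. Keep only points
# that advance along the running direction (exponential moving average of
# accepted steps, seeded with the end-to-end direction).
filter_backtrack <- function(pts, min_step = 1e-6, alpha = 0.3) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  dir_run <- unitize(pts[n, ] - pts[1, ])
  keep <- logical(n)
  keep[1] <- TRUE
  last <- pts[1, ]
  for (i in 2:n) {
    v <- pts[i, ] - last
    nv <- sqrt(sum(v^2))
    if (nv < min_step) next
    if (sum(v * dir_run) / nv <= 0) next
    keep[i] <- TRUE
    last <- pts[i, ]
    dir_run <- unitize((1 - alpha) * dir_run + alpha * v / nv)
  }
  pts[keep, , drop = FALSE]
}

# Near weakly contracted regions (cap rings) the geodesic path winds inside
# a small blob before leaving it, inflating arc length without geometric
# progress. Collapse the longest leading run of points that stays within
# `radius` of the first point down to its last member.
trim_end_blob <- function(pts, radius, reverse = FALSE) {
  if (reverse) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  d <- sqrt(rowSums(sweep(pts, 2, pts[1, ])^2))
  outside <- which(d > radius)
  k <- if (length(outside) == 0) nrow(pts) else outside[1] - 1L
  if (k > 1) pts <- pts[-seq_len(k - 1L), , drop = FALSE]
  if (reverse) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Denoise an ordered point path. The raw geodesic path can locally zigzag
# (contracted mesh rings may overlap axially), which inflates its arc length
# without geometric progress; consecutive points are therefore grouped until
# the path leaves a ball of radius `bin_width` around the group's first
# point, each group is replaced by its centroid, and a natural cubic spline
# through the centroids (parameterized by inter-centroid distance) is
# resampled at even spacing.
smooth_path <- function(path_pts, bin_width, spacing) {
  n <- nrow(path_pts)
  group <- integer(n)
  g <- 1L
  anchor <- path_pts[1, ]
  for (i in seq_len(n)) {
    if (sqrt(sum((path_pts[i, ] - anchor)^2)) > bin_width) {
      g <- g + 1L
      anchor <- path_pts[i, ]
    }
    group[i] <- g
  }
  ctr <- cbind(tapply(path_pts[, 1], group, mean),
               tapply(path_pts[, 2], group, mean),
               tapply(path_pts[, 3], group, mean))
  if (nrow(ctr) < 4) stop("skeleton path too short to smooth", call. = FALSE)
  cs <- c(0, cumsum(sqrt(rowSums(diff(ctr)^2))))
  L <- max(cs)
  if (L <= spacing) stop("skeleton path too short to smooth", call. = FALSE)
  ss <- seq(0, L, length.out = max(50L, ceiling(L / 0.25)))
  sp <- cbind(stats::spline(cs, ctr[, 1], xout = ss, method = "natural")$y,
              stats::spline(cs, ctr[, 2], xout = ss, method = "natural")$y,
              stats::spline(cs, ctr[, 3], xout = ss, method = "natural")$y)
  resample_centerline(centerline(sp), spacing)
}

#' Extract a centerline by Laplacian-based contraction
#'
#' Contracts the mesh onto its medial curve (see [lbc_params()]), prunes the
#' contracted cloud to the longest geodesic path through the mesh edge graph
#' (discarding side branches), denoises and spline-smooths the path, and
#' resamples it at even arc-length spacing. When `landmarks` are supplied,
#' the curve is oriented so arc length 0 lies at the left-ventricular end:
#' the end farther along the path from the annulus centroid (the mean of the
#' three nadirs).
#'
#' @param mesh A [surface_mesh()]. For meshes with several components the
#'   largest (the aortic root + LV shell) is skeletonized.
#' @param params Parameters from [lbc_params()].
#' @param landmarks Optional [landmark_set()] fixing the orientation.
#' @return A [centerline()] with attribute `"diagnostics"` (iterations, area
#'   ratio, displacement history).
#' @export
extract_centerline_lbc <- function(mesh, params = lbc_params(), landmarks = NULL) {
  contr <- contract_mesh(mesh, params)
  path_pts <- skeleton_path(mesh, contr$positions)
  cl <- smooth_path(path_pts, params$bin_width, params$spacing)
  if ((params$refine_iterations %||% 0) > 0) {
    cl <- refine_centerline(mesh, cl, params$refine_iterations, params$spacing)
  }
  if (!is.null(landmarks)) {
    cl <- orient_centerline(cl, landmarks)
  }
  attr(cl, "diagnostics") <- list(iterations = contr$iterations,
                                  area_ratio = contr$area_ratio,
                                  displacement = contr$displacement)
  cl
}

# Re-center stations on the centroid of the cross-section perpendicular to
# the local tangent (the centroid of an oblique tube section lies on the
# tube axis). Stations whose section fails, or whose centroid moves
# implausibly far (cap grazing, branch jumps), are rejected; the curve is
# truncated to the accepted range and re-fit with a smoothing spline, which
# suppresses the station-level noise the raw contraction skeleton carries.
refine_centerline <- function(mesh, cl, iterations, spacing, max_move = 2.5) {
  for (it in seq_len(iterations)) {
    pts <- cl$points
    n <- nrow(pts)
    ok <- logical(n)
    for (i in seq_len(n)) {
      tg <- tangent_at(cl, cl$arclength[i])
      sec <- tryCatch(slice_mesh(mesh, plane(pts[i, ], tg), anchor = pts[i, ]),
                      error = function(e) NULL)
      if (!is.null(sec) && vnorm(sec$centroid - pts[i, ]) < max_move) {
        pts[i, ] <- sec$centroid
        ok[i] <- TRUE
      }
    }
    if (sum(ok) < 10) return(cl)      # refinement not applicable; keep curve
    rng <- range(which(ok))
    keep <- seq(rng[1], rng[2])
    s <- cl$arclength[keep][ok[keep]]
    p <- pts[keep, , drop = FALSE][ok[keep], , drop = FALSE]
    L <- max(s) - min(s)
    df <- max(6, min(length(s) - 1, round(L / 6)))
    ss <- seq(min(s), max(s), length.out = max(50L, ceiling(L / 0.25)))
    sp <- cbind(stats::predict(stats::smooth.spline(s, p[, 1], df = df), ss)$y,
                stats::predict(stats::smooth.spline(s, p[, 2], df = df), ss)$y,
                stats::predict(stats::smooth.spline(s, p[, 3], df = df), ss)$y)
    cl <- resample_centerline(centerline(sp), spacing)
  }
  cl
}

# Flip the centerline, if needed, so s = 0 is the LV end (the end farther
# along the curve from the nadir centroid).
orient_centerline <- function(cl, landmarks) {
  ac <- colMeans(nadir_matrix(landmarks))
  d <- sqrt(rowSums(sweep(cl$points, 2, ac)^2))
  s_ann <- cl$arclength[which.min(d)]
  if (s_ann < centerline_length(cl) / 2) {
    cl <- centerline(cl$points[rev(seq_len(nrow(cl$points))), , drop = FALSE])
  }
  cl
}
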