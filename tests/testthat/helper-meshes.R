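# Programmatic mesh fixtures and independent oracles used across the suite.

# Closed capped cylinder (or elliptic cylinder) along +z, z in [0, L].
make_cylinder_mesh <- function(r = 10, L = 80, nc = 64, nz = 40, ry = r,
                               center = c(0, 0, 0)) {
  phi <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  z <- seq(0, L, length.out = nz + 1)
  verts <- do.call(rbind, lapply(z, function(zz) {
    cbind(r * cos(phi), ry * sin(phi), zz)
  }))
  idx <- function(i, k) (i - 1L) * nc + k
  i <- rep(seq_len(nz), each = nc)
  k <- rep(seq_len(nc), nz)
  k2 <- k %% nc + 1L
  f <- rbind(cbind(idx(i, k), idx(i, k2), idx(i + 1L, k)),
             cbind(idx(i + 1L, k), idx(i, k2), idx(i + 1L, k2)))
  nb <- nrow(verts)
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, L))
  kk <- seq_len(nc); kk2 <- kk %% nc + 1L
  f <- rbind(f,
             cbind(nb + 1L, idx(1L, kk2), idx(1L, kk)),
             cbind(nb + 2L, idx(nz + 1L, kk), idx(nz + 1L, kk2)))
  surface_mesh(sweep(verts, 2, center, "+"), f)
}

# Closed tube swept along a circular arc of radius R_curv in the x-z plane
# (arc length L), circular cross-section radius r.
make_arc_tube_mesh <- function(r = 10, R_curv = 60, L = 80, nc = 64, nz = 80) {
  phi <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  s <- seq(0, L, length.out = nz + 1)
  verts <- do.call(rbind, lapply(s, function(si) {
    a <- si / R_curv
    C <- c(R_curv - R_curv * cos(a), 0, R_curv * sin(a))
    Nv <- c(cos(a), 0, -sin(a)); B <- c(0, 1, 0)
    t(C + r * (outer(Nv, cos(phi)) + outer(B, sin(phi))))
  }))
  idx <- function(i, k) (i - 1L) * nc + k
  i <- rep(seq_len(nz), each = nc)
  k <- rep(seq_len(nc), nz)
  k2 <- k %% nc + 1L
  f <- rbind(cbind(idx(i, k), idx(i, k2), idx(i + 1L, k)),
             cbind(idx(i + 1L, k), idx(i, k2), idx(i + 1L, k2)))
  nb <- nrow(verts)
  ends <- rbind(c(0, 0, 0),
                c(R_curv - R_curv * cos(L / R_curv), 0, R_curv * sin(L / R_curv)))
  verts <- rbind(verts, ends)
  kk <- seq_len(nc); kk2 <- kk %% nc + 1L
  f <- rbind(f,
             cbind(nb + 1L, idx(1L, kk2), idx(1L, kk)),
             cbind(nb + 2L, idx(nz + 1L, kk), idx(nz + 1L, kk2)))
  surface_mesh(verts, f)
}

# Unit-style cube mesh: 8 vertices, 12 faces, edge a, corner at origin.
make_cube_mesh <- function(a = 10) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, a), z = c(0, a)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = a
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = a
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6)       # x = a
  )
  surface_mesh(v, f)
}

# Independent Euler/edge-count watertightness oracle (no shared code with
# validate_mesh's half-edge bookkeeping): per connected component of the
# face graph, V - E + F must equal 2 and every edge must occur exactly twice.
euler_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  g <- igraph::graph_from_edgelist(unique(cbind(pmin(e[, 1], e[, 2]),
                                                pmax(e[, 1], e[, 2]))),
                                   directed = FALSE)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    nf <- sum(rowSums(matrix(f %in% vs, ncol = 3)) == 3)
    ne <- length(unique(key[e[, 1] %in% vs]))
    if (length(vs) - ne + nf != 2) return(FALSE)
  }
  TRUE
}

# Independent polygon oracle: area via Green's theorem (integral x dy),
# perimeter by explicit loop, centroid via signed triangle-fan decomposition
# about an arbitrary exterior reference point.
oracle_polygon_metrics <- function(xy) {
  n <- nrow(xy)
  area <- 0; per <- 0
  cx <- 0; cy <- 0
  ref <- c(min(xy[, 1]) - 17.3, min(xy[, 2]) - 9.1)
  for (i in seq_len(n)) {
    p <- xy[i, ]; q <- xy[if (i == n) 1 else i + 1, ]
    area <- area + p[1] * (q[2] - p[2]) + 0.5 * (q[1] - p[1]) * (q[2] - p[2])
    per <- per + sqrt(sum((q - p)^2))
    a2 <- ((p[1] - ref[1]) * (q[2] - ref[2]) - (q[1] - ref[1]) * (p[2] - ref[2])) / 2
    cen <- (p + q + ref) / 3
    cx <- cx + a2 * cen[1]; cy <- cy + a2 * cen[2]
  }
  list(area = area, perimeter = per, centroid = c(cx, cy) / area)
}

# Random star-shaped simple polygon around the origin.
random_star_polygon <- function(n = 24, r_min = 3, r_max = 12) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}

# Small fast phantom spec for tests that only need a working anatomy.
fast_phantom <- function(...) {
  generate_phantom(phantom_spec(n_circ = 48, axial_spacing = 1, ...))
}

# Digital ball mask: 3D array with 1 inside a sphere, center in 0-based
# voxel coordinates.
make_ball_mask <- function(dm, center0, radius) {
  arr <- array(0, dm)
  ix <- arrayInd(seq_len(prod(dm)), dm) - 1
  d2 <- (ix[, 1] - center0[1])^2 + (ix[, 2] - center0[2])^2 + (ix[, 3] - center0[3])^2
  arr[d2 <= radius^2] <- 1
  arr
}
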