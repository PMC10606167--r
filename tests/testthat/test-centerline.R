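test_that("resampling preserves endpoints, counts and arc length", {
  cl <- centerline(cbind(0, 0, c(0, 4, 10)))
  r1 <- resample_centerline(cl, 1)
  expect_equal(nrow(r1$points), 11)
  expect_equal(r1$points[1, ], c(0, 0, 0))
  expect_equal(r1$points[11, ], c(0, 0, 10))
  r2 <- resample_centerline(r1, 1)
  expect_lt(max(abs(r2$points - r1$points)), 1e-9)

  # semicircle radius 10: length 10*pi, spacing 1 -> 32 points
  th <- seq(0, pi, length.out = 2001)
  semi <- centerline(cbind(10 * cos(th), 10 * sin(th), 0))
  rs <- resample_centerline(semi, 1)
  expect_equal(nrow(rs$points), 32)
  chord_sum <- sum(sqrt(rowSums(diff(rs$points)^2)))
  expect_lt(abs(chord_sum - 10 * pi) / (10 * pi), 0.005)

  expect_error(resample_centerline(centerline(cbind(0, 0, c(0, 0.1))), 1),
               "shorter")
})

test_that("tangents are unit, continuous, and geometrically correct", {
  cl <- resample_centerline(centerline(cbind(0, 0, seq(0, 50, 5))), 1)
  for (s in c(0, 7.3, 25, 50)) {
    expect_equal(tangent_at(cl, s), c(0, 0, 1), tolerance = 1e-12)
  }
  set.seed(5)
  th <- seq(0, pi / 2, length.out = 500)
  arc <- centerline(cbind(30 * cos(th), 30 * sin(th), 0))
  ss <- runif(100, 0, tavimetrics:::centerline_length(arc))
  tg <- tangent_at(arc, ss)
  expect_true(all(abs(sqrt(rowSums(tg^2)) - 1) < 1e-9))
  # tangent perpendicular to the radius vector within 1 degree
  pts <- tavimetrics:::centerline_point_at(arc, ss)
  cosang <- abs(rowSums(tg * pts) / sqrt(rowSums(pts^2)))
  expect_true(all(cosang < sin(pi / 180)))
  expect_error(tangent_at(arc, -5), "out of range")
})

test_that("marching follows the cylinder axis and recovers from a tilted seed", {
  m <- make_cylinder_mesh(r = 10, L = 80, nc = 64, nz = 80)
  cl <- extract_centerline_marching(m, plane(c(0, 0, 40), c(0, 0, 1)))
  expect_lt(max(sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)), 1e-3)
  expect_gt(tavimetrics:::centerline_length(cl), 70)

  tilt <- plane(c(0, 0, 40), c(sin(20 * pi / 180), 0, cos(20 * pi / 180)))
  clt <- extract_centerline_marching(m, tilt)
  # direction after the first few stations aligns with the axis within 1 deg
  i0 <- which.min(abs(clt$points[, 3] - 40))
  seg <- clt$points[min(i0 + 5, nrow(clt$points)), ] - clt$points[i0, ]
  ang <- acos(abs(seg[3]) / sqrt(sum(seg^2))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("contraction centerline tracks the cylinder axis within 0.5 mm", {
  m <- make_cylinder_mesh(r = 10, L = 80, nc = 64, nz = 80)
  cl <- extract_centerline_lbc(m)
  L <- tavimetrics:::centerline_length(cl)
  mid <- cl$arclength > 0.05 * L & cl$arclength < 0.95 * L
  dev <- sqrt(cl$points[mid, 1]^2 + cl$points[mid, 2]^2)
  expect_lt(max(dev), 0.5)
  expect_lte(max(diff(cl$arclength)), 1.0)
  expect_true(all(diff(cl$arclength) > 0))
  expect_true(all(points_in_mesh(m, cl$points)))
})

test_that("contraction centerline is rigidly equivariant", {
  m <- make_cylinder_mesh(r = 8, L = 60, nc = 48, nz = 60)
  cl <- extract_centerline_lbc(m)
  set.seed(13)
  tr <- random_rigid_transform()
  cl_t <- extract_centerline_lbc(transform_mesh(m, tr))
  a <- apply_rigid(cl$points, tr)
  b <- cl_t$points
  # allow opposite traversal order
  d_fwd <- max(sqrt(rowSums((tavimetrics:::centerline_point_at(
    cl_t, cl$arclength / max(cl$arclength) * max(cl_t$arclength)) - a)^2)))
  d_rev <- max(sqrt(rowSums((tavimetrics:::centerline_point_at(
    cl_t, (1 - cl$arclength / max(cl$arclength)) * max(cl_t$arclength)) - a)^2)))
  expect_lt(min(d_fwd, d_rev), 0.5)
})

test_that("curved-tube centerline stays within 1 mm of the generating arc", {
  m <- make_arc_tube_mesh(r = 10, R_curv = 60, L = 80, nc = 48, nz = 80)
  cl <- extract_centerline_lbc(m)
  P <- cl$points
  dev <- sqrt((sqrt((P[, 1] - 60)^2 + P[, 3]^2) - 60)^2 + P[, 2]^2)
  L <- tavimetrics:::centerline_length(cl)
  mid <- cl$arclength > 0.05 * L & cl$arclength < 0.95 * L
  expect_lt(max(dev[mid]), 1)
  expect_true(all(points_in_mesh(m, P)))

  # cross-method agreement with the marching extractor
  clm <- extract_centerline_marching(m, plane(c(60 - 60 * cos(0.5), 0, 60 * sin(0.5)),
                                              c(sin(0.5), 0, cos(0.5))))
  Q <- clm$points
  dev_m <- sqrt((sqrt((Q[, 1] - 60)^2 + Q[, 3]^2) - 60)^2 + Q[, 2]^2)
  rms <- function(x) sqrt(mean(x^2))
  # both lie near the same generating arc -> cross-method RMS bounded
  expect_lt(rms(dev[mid]) + rms(dev_m), 1.5)
})

test_that("pipeline orientation puts arc length zero at the LV end", {
  ph <- fast_phantom()
  cl <- extract_centerline_lbc(ph$mesh, landmarks = ph$landmarks)
  # LV end of the phantom is at z = 0, aorta at z = 90
  expect_lt(cl$points[1, 3], cl$points[nrow(cl$points), 3])
})
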