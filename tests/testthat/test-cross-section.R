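test_that("cylinder sections recover closed-form area and perimeter", {
  m <- make_cylinder_mesh(r = 10, L = 80, nc = 128, nz = 80)
  expect_gte(nrow(m$faces), 20000)
  sec <- slice_mesh(m, plane(c(0, 0, 40), c(0, 0, 1)), anchor = c(0, 0, 40))
  expect_lt(abs(sec$area - pi * 100) / (pi * 100), 0.005)
  expect_lt(abs(sec$perimeter - 2 * pi * 10) / (2 * pi * 10), 0.005)
  expect_lt(sqrt(sum((sec$centroid - c(0, 0, 40))^2)), 1e-6)

  # oblique cut at 60 degrees: area pi r^2 / cos(60)
  n60 <- c(sin(pi / 3), 0, cos(pi / 3))
  sec60 <- slice_mesh(m, plane(c(0, 0, 40), n60), anchor = c(0, 0, 40))
  expect_lt(abs(sec60$area - 2 * pi * 100) / (2 * pi * 100), 0.005)
})

test_that("area error shrinks with mesh refinement", {
  errs <- vapply(c(16, 32, 64, 128), function(nc) {
    m <- make_cylinder_mesh(r = 10, L = 10, nc = nc, nz = 4)
    sec <- slice_mesh(m, plane(c(0, 0, 5), c(0, 0, 1)), anchor = c(0, 0, 5))
    abs(sec$area - pi * 100) / (pi * 100)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 0.001)
})

test_that("elliptic sections give the axis diameters", {
  m <- make_cylinder_mesh(r = 15, ry = 10, L = 20, nc = 128, nz = 8)
  sec <- slice_mesh(m, plane(c(0, 0, 10), c(0, 0, 1)), anchor = c(0, 0, 10))
  mm <- min_max_diameters(sec, 0.5)
  expect_lt(abs(mm$d_min - 20) / 20, 0.01)
  expect_lt(abs(mm$d_max - 30) / 30, 0.01)
})

test_that("anchor containment picks the right loop of a two-lobed mesh", {
  a <- make_cylinder_mesh(r = 5, L = 30, nc = 24, nz = 8, center = c(-10, 0, 0))
  b <- make_cylinder_mesh(r = 7, L = 30, nc = 24, nz = 8, center = c(10, 0, 0))
  two <- surface_mesh(rbind(a$vertices, b$vertices),
                      rbind(a$faces, b$faces + nrow(a$vertices)))
  pl <- plane(c(0, 0, 15), c(0, 0, 1))
  sec_a <- slice_mesh(two, pl, anchor = c(-10, 0, 15))
  sec_b <- slice_mesh(two, pl, anchor = c(10, 0, 15))
  expect_lt(abs(sec_a$area - pi * 25) / (pi * 25), 0.02)
  expect_lt(abs(sec_b$area - pi * 49) / (pi * 49), 0.02)
  # in-polygon oracle on the selected contours
  expect_true(tavimetrics:::point_in_polygon(
    tavimetrics:::plane_to_2d(pl, c(-10, 0, 15), sec_a$basis)[1, ], sec_a$contour2d))
  expect_false(tavimetrics:::point_in_polygon(
    tavimetrics:::plane_to_2d(pl, c(-10, 0, 15), sec_b$basis)[1, ], sec_b$contour2d))
  # anchor outside every loop falls back to the nearest centroid
  sec_n <- slice_mesh(two, pl, anchor = c(4, 0, 15))
  expect_equal(sec_n$area, sec_b$area)
})

test_that("a plane missing the mesh raises an empty-section error", {
  m <- make_cylinder_mesh(r = 5, L = 10, nc = 16, nz = 4)
  expect_error(slice_mesh(m, plane(c(0, 0, 50), c(0, 0, 1)), anchor = c(0, 0, 50)),
               "empty section")
})

test_that("polygon metrics match an independent 2D oracle", {
  set.seed(7)
  for (k in 1:100) {
    xy <- random_star_polygon(n = sample(5:40, 1))
    area <- tavimetrics:::polygon_signed_area(xy)
    per <- tavimetrics:::polygon_perimeter(xy)
    cen <- tavimetrics:::polygon_centroid(xy)
    orc <- oracle_polygon_metrics(xy)
    expect_lt(abs(area - orc$area) / abs(orc$area), 1e-9)
    expect_lt(abs(per - orc$perimeter) / orc$perimeter, 1e-9)
    expect_lt(sqrt(sum((cen - orc$centroid)^2)), 1e-9)
  }
})

test_that("coarse chord scan agrees with the fine brute-force scan", {
  set.seed(11)
  ph <- fast_phantom()
  rep <- run_pipeline(ph$mesh, ph$landmarks)
  det <- attr(rep, "detail")
  for (sec in list(det$annulus_section, det$lvot_section, det$sov_section)) {
    coarse <- min_max_diameters(sec, 0.5)
    fine_len <- tavimetrics:::chord_scan(sec$contour2d, sec$centroid2d,
                                         seq(0, 179.995, by = 0.01))
    expect_lt(abs(coarse$d_min - min(fine_len, na.rm = TRUE)) / coarse$d_min, 0.0025)
    expect_lt(abs(coarse$d_max - max(fine_len, na.rm = TRUE)) / coarse$d_max, 0.0025)
  }
})

test_that("derived diameters follow the circle-equivalent formulas", {
  dd <- derived_diameters(490.87, 78.54)
  expect_equal(dd$d_area, 2 * sqrt(490.87 / pi), tolerance = 1e-12)
  expect_equal(dd$d_perim, 78.54 / pi, tolerance = 1e-12)
  expect_equal(derived_diameters(pi * 12.5^2, 2 * pi * 12.5)$d_area, 25)
  expect_equal(derived_diameters(pi * 12.5^2, 2 * pi * 12.5)$d_perim, 25)
  expect_error(derived_diameters(-1, 10), "positive")
  # isoperimetric: d_perim >= d_area on arbitrary star polygons
  set.seed(3)
  for (k in 1:20) {
    xy <- random_star_polygon()
    dd <- derived_diameters(abs(tavimetrics:::polygon_signed_area(xy)),
                            tavimetrics:::polygon_perimeter(xy))
    expect_gte(dd$d_perim, dd$d_area)
  }
})

test_that("area profile is flat on a cylinder and peaks at a bulge", {
  m <- make_cylinder_mesh(r = 10, L = 40, nc = 48, nz = 40)
  cl <- centerline(cbind(0, 0, seq(2, 38, by = 0.5)))
  prof <- area_profile(m, cl, 8, 28, spacing = 1)
  expect_equal(length(prof$s), 21)
  expect_true(all(abs(prof$area - pi * 100) / (pi * 100) < 0.005))

  # Gaussian-bulge tube: argmax of the profile at the bulge center
  s0 <- 20
  phi <- seq(0, 2 * pi, length.out = 49)[-49]
  z <- seq(0, 40, length.out = 41)
  verts <- do.call(rbind, lapply(z, function(zz) {
    r <- 10 + 3 * exp(-(zz - s0)^2 / (2 * 4^2))
    cbind(r * cos(phi), r * sin(phi), zz)
  }))
  base <- make_cylinder_mesh(r = 10, L = 40, nc = 48, nz = 40)
  bulged <- surface_mesh(rbind(verts, c(0, 0, 0), c(0, 0, 40)),
                         base$faces)
  prof2 <- area_profile(bulged, cl, 10, 30, spacing = 1)
  # the centerline starts at z = 2, so station s corresponds to z = s + 2
  expect_lte(abs((prof2$s[which.max(prof2$area)] + 2) - s0), 1 + 1e-9)
})

test_that("area profile is invariant under rigid transforms", {
  ph <- fast_phantom()
  cl <- centerline(cbind(0, 0, seq(30, 70, by = 0.5)))
  prof <- area_profile(ph$mesh, cl, 5, 35, spacing = 2)
  set.seed(21)
  tr <- random_rigid_transform()
  prof_t <- area_profile(transform_mesh(ph$mesh, tr), transform_centerline(cl, tr),
                         5, 35, spacing = 2)
  expect_lt(max(abs(prof$area - prof_t$area) / prof$area, na.rm = TRUE), 1e-6)
})
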