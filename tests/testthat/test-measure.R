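straight_cl <- function(z0 = 0, z1 = 90) {
  centerline(cbind(0, 0, seq(z0, z1, by = 0.5)))
}

test_that("annulus plane passes through the nadirs with the flow-aligned normal", {
  nad <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  cl_up <- straight_cl(-10, 10)
  pl <- annulus_plane(nad, cl_up)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin, c(1 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_lt(max(abs(plane_signed_distance(pl, nad))), 1e-9)

  cl_down <- centerline(cbind(0, 0, seq(10, -10, by = -0.5)))
  pl_down <- annulus_plane(nad, cl_down)
  expect_equal(pl_down$normal, c(0, 0, -1), tolerance = 1e-12)

  # tilted nadir plane: recovered normal within 0.01 degree of construction
  th <- 10 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  nad_t <- nad %*% t(Rx)
  pl_t <- annulus_plane(nad_t, cl_up)
  true_n <- as.numeric(Rx %*% c(0, 0, 1))
  expect_lt(acos(min(1, sum(pl_t$normal * true_n))) * 180 / pi, 0.01)

  expect_error(annulus_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), cl_up),
               "implausible")
})

test_that("the LVOT plane is a pure translation along the centerline", {
  nad <- rbind(c(12, 0, 40), c(-6, 10.4, 40), c(-6, -10.4, 40))
  cl <- straight_cl(0, 90)
  ann <- annulus_plane(nad, cl)
  lv <- lvot_plane(ann, cl, 4)
  expect_equal(lv$origin, c(0, 0, 36), tolerance = 1e-9)
  expect_identical(lv$normal, ann$normal)
  lv0 <- lvot_plane(ann, cl, 0)
  expect_equal(lv0$origin, c(0, 0, 40), tolerance = 1e-9)

  # curved centerline: straight-line offset cannot exceed the arc offset
  th <- seq(0, pi / 2, length.out = 500)
  arc <- centerline(cbind(60 - 60 * cos(th), 0, 60 * sin(th)))
  p40 <- tavimetrics:::centerline_point_at(arc, 40)
  # place nadirs in the plane perpendicular to the arc tangent at s=40
  tg <- tangent_at(arc, 40)
  b <- tavimetrics:::plane_basis(plane(as.numeric(p40), tg))
  nad_c <- t(vapply(list(c(12, 0), c(-6, 10.4), c(-6, -10.4)), function(u) {
    as.numeric(p40) + u[1] * b$u + u[2] * b$v
  }, numeric(3)))
  ann_c <- annulus_plane(nad_c, arc)
  lv_c <- lvot_plane(ann_c, arc, 4)
  expect_lte(sqrt(sum((lv_c$origin - ann_c$origin)^2)), 4 + 1e-9)
  expect_error(lvot_plane(ann, straight_cl(38, 90), 4), "too short")
})

test_that("nadir perturbations propagate identically to the LVOT plane", {
  ph <- fast_phantom()
  cl <- straight_cl(10, 85)
  lm <- perturb_landmarks(ph$landmarks, 1.5, seed = 99)
  ann <- annulus_plane(lm, cl)
  lv <- lvot_plane(ann, cl, 4)
  expect_identical(lv$normal, ann$normal)
})

test_that("SOV/SNTJ detection finds the bulge peak and the plateau onset", {
  # synthetic profile: raised-cosine bulge then exact plateau
  s <- 0:40
  area <- 600 + 140 * ifelse(abs(s - 10) < 8, 0.5 + 0.5 * cos(2 * pi * (s - 10) / 16), 0)
  prof <- structure(list(s = s, area = area, sections = vector("list", length(s))),
                    class = "area_profile")
  res <- find_sov_sntj(prof, s_annulus = 0)
  expect_equal(res$s_sov, 10)
  expect_lte(abs(res$s_sntj - 18), 2)
  expect_length(res$qc_flags, 0)

  # monotone cone: argmax at the boundary raises the QC flag
  cone <- structure(list(s = s, area = 300 + 5 * s,
                         sections = vector("list", length(s))),
                    class = "area_profile")
  res_cone <- find_sov_sntj(cone, s_annulus = 0, sntj_rel_tol = 0.001)
  expect_true("SOV at search boundary" %in% res_cone$qc_flags)

  # never-stabilizing profile: fallback flag raised
  steep <- structure(list(s = 0:15, area = c(500 + 50 * (0:5), 800 - 60 * (1:10)),
                          sections = vector("list", 16)),
                     class = "area_profile")
  res_fb <- find_sov_sntj(steep, s_annulus = 0, sntj_rel_tol = 0.0005)
  expect_true("SNTJ stabilization fallback" %in% res_fb$qc_flags)
  expect_gt(res_fb$s_sntj, res_fb$s_sov)

  short <- structure(list(s = 0:5, area = rep(500, 6), sections = vector("list", 6)),
                     class = "area_profile")
  expect_error(find_sov_sntj(short, s_annulus = 0), "valid stations")
})

test_that("sinus diameters on a circular section are all full diameters", {
  m <- make_cylinder_mesh(r = 17, L = 30, nc = 96, nz = 10)
  sec <- slice_mesh(m, plane(c(0, 0, 15), c(0, 0, 1)), anchor = c(0, 0, 15))
  lm <- landmark_set(left_coronary_ostium = c(0, 17, 28),
                     right_coronary_ostium = c(14.7, -8.5, 27),
                     nadir_left = c(0, 12.5, 2),
                     nadir_right = c(10.8, -6.2, 2),
                     nadir_noncoronary = c(-10.8, -6.2, 2))
  sd <- sinus_diameters(sec, lm)
  for (d in sd$diameters) expect_lt(abs(d - 34) / 34, 0.002)
})

test_that("asymmetric sinus lobes order the recovered diameters", {
  ph <- generate_phantom(phantom_spec(r_sinus_lcc = 18, r_sinus_rcc = 16,
                                      r_sinus_ncc = 17, n_circ = 48,
                                      axial_spacing = 1))
  rep <- run_pipeline(ph$mesh, ph$landmarks)
  d <- rep$sov
  expect_gt(d["diameter_lcc"], d["diameter_ncc"])
  expect_gt(d["diameter_ncc"], d["diameter_rcc"])
  tv <- ph$truth$report$sov
  expect_lt(max(abs(d - tv) / tv), 0.01)
})

test_that("coronary heights are perpendicular distances to the annulus plane", {
  pl <- plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(coronary_height(c(5, -3, 12), pl), 12)
  expect_equal(coronary_height(c(7, 2, 0), pl), 0)
  expect_equal(coronary_height(c(0, 0, -3), pl), -3)
})

test_that("the pipeline emits 22 QC-clean measurements on the default phantom", {
  ph <- fast_phantom()
  rep <- run_pipeline(ph$mesh, ph$landmarks)
  vals <- tavimetrics:::report_values(rep)
  expect_length(vals, 22)
  expect_true(all(is.finite(vals)))
  expect_length(rep$metadata$qc_flags, 0)
  expect_s3_class(validate_report(rep), "measurement_report")
})

test_that("stage errors carry the failing stage name", {
  ph <- fast_phantom()
  lm <- ph$landmarks
  # degenerate nadir geometry injected past the constructor checks
  lm$nadir_left <- c(0, 0, 50)
  lm$nadir_right <- c(1, 0, 50)
  lm$nadir_noncoronary <- c(2, 1e-8, 50)
  err <- tryCatch(run_pipeline(ph$mesh, lm, measure_config(
    centerline_method = "marching")),
    error = function(e) e)
  expect_s3_class(err, "pipeline_stage_error")
})

test_that("allow_partial degrades to NA fields with QC flags", {
  ph <- fast_phantom()
  # truncated centerline: no stations above the annulus -> SOV stage fails
  cl <- centerline(cbind(0, 0, seq(10, 55, by = 0.5)))
  cfg <- measure_config(allow_partial = TRUE)
  rep <- run_pipeline(ph$mesh, ph$landmarks, cfg, centerline = cl)
  expect_true(any(grepl("partial", rep$metadata$qc_flags)))
  expect_true(all(is.na(rep$sntj)))
  expect_true(all(is.finite(rep$annulus)))
  cfg_strict <- measure_config(allow_partial = FALSE)
  expect_error(run_pipeline(ph$mesh, ph$landmarks, cfg_strict, centerline = cl),
               class = "pipeline_stage_error")
})

test_that("unknown config keys are rejected and defaults echo into metadata", {
  expect_error(tavimetrics:::config_from_list(list(plane_spacing = 1)), "unknown")
  ph <- fast_phantom()
  rep <- run_pipeline(ph$mesh, ph$landmarks)
  expect_equal(rep$metadata$config$lvot_offset_mm, 4)
  expect_equal(rep$metadata$config$plane_spacing_mm, 1)
})
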