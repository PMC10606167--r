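test_that("phantom truth matches closed forms", {
  tr <- phantom_truth(phantom_spec())
  expect_equal(unname(tr$report$annulus["area"]), pi * 12.5^2, tolerance = 1e-9)
  expect_equal(unname(tr$report$annulus["perimeter"]), 2 * pi * 12.5, tolerance = 1e-9)
  expect_equal(unname(tr$report$coronary["height_left"]), 14, tolerance = 1e-9)
  expect_equal(unname(tr$report$coronary["height_right"]), 12, tolerance = 1e-9)
  expect_equal(tr$s_sov - tr$s_annulus, 10)
  expect_equal(tr$s_sntj - tr$s_annulus, 18)
  expect_equal(unname(tr$report$sntj["diameter_avg"]), 28, tolerance = 1e-9)
  # symmetric default: every sinus line hits the lobe peak (17) and the
  # opposite inter-lobe trough (14)
  expect_equal(unname(tr$report$sov), rep(31, 3), tolerance = 1e-3)
  expect_s3_class(validate_report(tr$report), "measurement_report")
})

test_that("a featureless spec degenerates to a cylinder", {
  spec <- phantom_spec(r_lvot = 10, r_annulus = 10, r_stj = 10,
                       r_sinus_lcc = 10.05, r_sinus_rcc = 10.05,
                       r_sinus_ncc = 10.05, n_circ = 48, axial_spacing = 1)
  tr <- phantom_truth(spec)
  expect_equal(unname(tr$report$annulus["area"]), pi * 100, tolerance = 1e-9)
  ph <- generate_phantom(spec)
  # every mesh vertex lies within the tiny bulge band of radius 10
  rad <- sqrt(ph$mesh$vertices[, 1]^2 + ph$mesh$vertices[, 2]^2)
  interior <- abs(ph$mesh$vertices[, 3] - 45) < 44
  expect_true(all(rad[interior] <= 10.06))
})

test_that("phantom generation is deterministic and noise is bounded", {
  s1 <- phantom_spec(noise = 0, seed = 1)
  s2 <- phantom_spec(noise = 0, seed = 2)
  expect_identical(generate_phantom(s1)$mesh$vertices,
                   generate_phantom(s2)$mesh$vertices)
  sn <- phantom_spec(noise = 0.1, seed = 3)
  a <- generate_phantom(sn)
  b <- generate_phantom(sn)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  clean <- generate_phantom(phantom_spec(noise = 0, seed = 3))
  dv <- sqrt(rowSums((a$mesh$vertices - clean$mesh$vertices)^2))
  expect_lte(max(dv), 0.1 + 1e-12)
  # truth is defined by the spec, not the noise draw
  expect_identical(tavimetrics:::report_values(a$truth$report),
                   tavimetrics:::report_values(clean$truth$report))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(r_annulus = -1), "positive")
  expect_error(phantom_spec(noise = 5), "noise")
  expect_error(phantom_spec(bulge_center = 2, bulge_width = 16), "support")
  expect_error(phantom_spec(curvature_radius = 20), "curvature")
  expect_error(phantom_spec(r_sinus_lcc = 13), "exceed")
})

test_that("phantom landmarks sit on the analytic surface and the mesh", {
  ph <- fast_phantom()
  lm <- ph$landmarks
  # nadirs on the annulus circle
  for (nm in c("nadir_left", "nadir_right", "nadir_noncoronary")) {
    expect_equal(sqrt(sum(lm[[nm]][1:2]^2)), 12.5, tolerance = 1e-9)
    expect_equal(lm[[nm]][3], 50, tolerance = 1e-9)
  }
  expect_equal(lm$left_coronary_ostium[3], 64, tolerance = 1e-9)
  expect_equal(lm$right_coronary_ostium[3], 62, tolerance = 1e-9)
})

test_that("landmark jitter has the chi-distribution displacement scale", {
  ph <- fast_phantom()
  expect_identical(perturb_landmarks(ph$landmarks, 0), ph$landmarks)
  p1 <- perturb_landmarks(ph$landmarks, 1, seed = 7)
  p2 <- perturb_landmarks(ph$landmarks, 1, seed = 7)
  expect_identical(p1, p2)
  sigma <- 2.01
  disp <- unlist(lapply(1:200, function(i) {
    p <- perturb_landmarks(ph$landmarks, sigma, seed = i)
    vapply(names(unclass(ph$landmarks)),
           function(nm) sqrt(sum((p[[nm]] - ph$landmarks[[nm]])^2)), 0)
  }))
  # E|N(0, sigma^2 I_3)| = sigma * sqrt(8 / pi) * (Gamma-ratio) = sigma * 1.5958
  expect_lt(abs(mean(disp) - sigma * sqrt(8 / pi)) / (sigma * sqrt(8 / pi)), 0.05)
})

test_that("coronary-height error grows with nadir jitter faster than area error", {
  ph <- fast_phantom()
  sens <- landmark_sensitivity(ph, sigmas = c(0, 0.5, 1, 2), n_draws = 60,
                               seed = 11, compute_area = TRUE)
  med_rch <- tapply(sens$rch_err, sens$sigma, median, na.rm = TRUE)
  med_area <- tapply(sens$area_rel_err, sens$sigma, median, na.rm = TRUE)
  expect_true(all(diff(med_rch) > 0))
  # relative scales at sigma = 2: height error (mm / 12 mm) dominates the
  # relative area error
  expect_gt(med_rch[["2"]] / 12, med_area[["2"]])
})
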