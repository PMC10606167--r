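test_that("the sqrt(n-1) confidence interval reproduces its printed example", {
  ci <- ci_eq1(10, 2, 5, 1.96)
  expect_equal(unname(ci), c(8.04, 11.96), tolerance = 1e-9)
  expect_equal(unname(ci_eq1(7, 0, 10)), c(7, 7))
  expect_equal(unname(ci_eq1(7, 2, 10, z = 0)), c(7, 7))
  # standard-error form available behind the flag
  ci_n <- ci_eq1(10, 2, 5, 1.96, denominator = "n")
  expect_equal(unname(ci_n), 10 + c(-1, 1) * 1.96 * 2 / sqrt(5), tolerance = 1e-12)
  expect_error(ci_eq1(1, 1, 1), "n >= 2")
})

test_that("mean absolute relative error uses the reference denominator", {
  b <- c(10, 20, 30, 40)
  expect_equal(mean_abs_rel_error(b, b)$mare, 0)
  expect_equal(mean_abs_rel_error(1.05 * b, b)$mare, 5, tolerance = 1e-12)
  expect_equal(mean_abs_rel_error(c(11, 9, 11, 9), c(10, 10, 10, 10))$mare, 10,
               tolerance = 1e-12)
  expect_warning(res <- mean_abs_rel_error(c(1, 2, 3), c(0, 2, 3)), "zero reference")
  expect_equal(res$n_excluded, 1)
})

test_that("Pearson correlation and Fisher interval match direct formulas", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_ci(a, 2 * a + 3)$r, 1)
  expect_equal(pearson_ci(a, -a)$r, -1)
  b <- c(2, 1, 4, 3, 6)
  res <- pearson_ci(a, b)
  # direct formula oracle
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$r, 10 / sqrt(148), tolerance = 1e-12)
  fz <- atanh(r_direct) + c(-1, 1) * 1.96 / sqrt(2)
  expect_equal(unname(res$ci), tanh(fz), tolerance = 1e-12)
  expect_error(pearson_ci(c(1, 1, 1, 1), c(1, 2, 3, 4)), "zero variance")
  expect_error(pearson_ci(a[1:3], b[1:3]), "n >= 4")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(31)
  a <- rnorm(50); b <- a + rnorm(50, sd = 0.4)
  r0 <- pearson_ci(a, b)$r
  expect_equal(pearson_ci(3 * a + 7, b)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_ci(a, 0.2 * b - 11)$r, r0, tolerance = 1e-12)
})

test_that("Bland-Altman limits reproduce the hand-computed example", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 31))
  d <- c(-2, 1, -1)
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  # printed-precision values
  expect_equal(round(ba$mean_diff, 3), -0.667)
  expect_equal(round(ba$loa_low, 2), -3.66)
  expect_equal(round(ba$loa_high, 2), 2.33)
  # swapping raters negates and mirrors
  ba_sw <- bland_altman(c(12, 19, 31), c(10, 20, 30))
  expect_equal(ba_sw$mean_diff, -ba$mean_diff)
  expect_equal(ba_sw$loa_low, -ba$loa_high)

  expect_equal(bland_altman(1:5, 1:5)$loa_low, 0)
})

test_that("limits of agreement cover ~95% of large Gaussian samples", {
  set.seed(41)
  a <- rnorm(5000, 25, 3)
  b <- a + rnorm(5000, 0.5, 1.2)
  ba <- bland_altman(a, b)
  inside <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  expect_gte(inside, 0.93)
})

test_that("paired tables align on case_id and feed the full analysis", {
  set.seed(51)
  n <- 40
  truthy <- data.frame(case_id = sprintf("case%02d", 1:n),
                       annulus_area = rnorm(n, 480, 60),
                       lch = rnorm(n, 13, 2))
  rater2 <- truthy
  rater2$annulus_area <- truthy$annulus_area * rnorm(n, 1, 0.03)
  rater2$lch <- truthy$lch + rnorm(n, 0, 0.8)
  pa <- tempfile(fileext = ".csv"); pb <- tempfile(fileext = ".csv")
  write.csv(truthy[sample(n), ], pa, row.names = FALSE)
  write.csv(rater2, pb, row.names = FALSE)
  paired <- read_paired_measurements(pa, pb)
  expect_equal(sort(paired$measurements), c("annulus_area", "lch"))
  res <- agreement_analysis(paired)
  expect_equal(nrow(res), 2)
  expect_true(all(res$ba_loa_low <= res$ba_mean_diff &
                  res$ba_mean_diff <= res$ba_loa_high))
  expect_true(all(res$pearson_r >= -1 & res$pearson_r <= 1))
  # identical tables: zero error, perfect correlation
  paired_id <- read_paired_measurements(pa, pa)
  res_id <- agreement_analysis(paired_id)
  expect_equal(res_id$mare_pct, c(0, 0))
  expect_equal(res_id$pearson_r, c(1, 1))

  bad <- truthy; bad$case_id <- paste0("x", bad$case_id)
  pc <- tempfile(fileext = ".csv")
  write.csv(bad, pc, row.names = FALSE)
  expect_error(read_paired_measurements(pa, pc), "shared case_ids")
})

test_that("agreement statistics match naive direct-formula oracles", {
  set.seed(61)
  for (k in 1:10) {
    a <- rnorm(30, 20, 4); b <- a + rnorm(30, 0, 1)
    res <- mean_abs_rel_error(a, b)
    expect_equal(res$mare, mean(abs(a - b) / abs(b)) * 100, tolerance = 1e-9)
    hw <- 1.96 * sd(abs(a - b) / abs(b) * 100) / sqrt(29)
    expect_equal(unname(res$ci), res$mare + c(-hw, hw), tolerance = 1e-9)
    ba <- bland_altman(a, b)
    expect_equal(ba$mean_diff, mean(a) - mean(b), tolerance = 1e-9)
    expect_equal(pearson_ci(a, b)$r, cor(a, b), tolerance = 1e-12)
  }
})
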