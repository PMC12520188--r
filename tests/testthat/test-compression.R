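test_that("disc area and height follow the pixel-count geometry rules", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE
  expect_equal(disc_area_from_mask(mask, 0.56), 100 * 0.56^2)
  expect_equal(disc_area_from_mask(matrix(TRUE, 1, 1), 1), 1)
  # translation leaves the count unchanged
  mask2 <- matrix(FALSE, 20, 20)
  mask2[6:15, 9:18] <- TRUE
  expect_equal(disc_area_from_mask(mask2, 0.56),
               disc_area_from_mask(mask, 0.56))
  expect_error(disc_area_from_mask(matrix(FALSE, 3, 3), 1), "empty mask")

  rect <- matrix(TRUE, 5, 20)
  expect_equal(disc_height_from_sagittal(rect, 1), 5)
  expect_equal(disc_height_from_sagittal(rect, 0.5), 2.5)
  # rasterized wedge spanning all 20 columns: mean height = area / AP width
  wedge <- outer(1:6, 1:20, function(r, c) r <= ceiling(6 * c / 20))
  expect_equal(disc_height_from_sagittal(wedge, 1), sum(wedge) / 20)
})

test_that("stress-strain normalization uses magnitudes and is homogeneous", {
  geo <- disc_geometry(417, 5)
  rec <- load_displacement_record(1:3, c(-0.5, -50, -100), c(-0.1, -0.3, -0.5))
  ss <- normalize_stress_strain(rec, geo)
  expect_equal(ss$stress_MPa[3], 100 / 417)  # ~0.24 MPa at -100 N
  expect_equal(ss$strain[3], 0.1)
  expect_true(all(ss$stress_MPa >= 0) && all(ss$strain >= 0))
  ss2 <- normalize_stress_strain(rec, disc_geometry(834, 5))
  expect_equal(ss2$stress_MPa, ss$stress_MPa / 2)
  # per-segment rezero references the first sample
  ss3 <- normalize_stress_strain(rec, geo, rezero = "segment")
  expect_equal(ss3$strain[1], 0)
})

test_that("cycle segmentation finds the declared ramps plus the creep hold", {
  geo <- disc_geometry(417, 5)
  rec <- generate_compression_test(2, 10, 0.03, geo)
  seg <- segment_cycles(rec)
  expect_length(seg$cycles, 20)
  expect_equal(seg$n_detected, 20)
  expect_false(is.null(seg$creep))
  expect_gte(diff(range(seg$creep$time_s)), 3599)
  # a truncated record names expected vs found
  short <- generate_compression_test(
    2, 10, 0.03, geo,
    protocols = acquisition_protocols(compression_cycles = 5, creep_hold_s = 60)
  )
  expect_error(segment_cycles(short, n_cycles = 20), "expected 20.*found 5")
})

test_that("noise inside the hysteresis band does not split cycles", {
  geo <- disc_geometry(417, 5)
  rec <- generate_compression_test(2, 10, 0.03, geo)
  # jitter the force trace by less than the 20 % band around -0.5 N
  set.seed(9)
  rec$force_N <- rec$force_N + runif(nrow(rec), -0.08, 0.08)
  seg <- segment_cycles(rec)
  expect_length(seg$cycles, 20)
})

test_that("bilinear fit recovers exact curves and satisfies line nesting", {
  f <- bilinear_fit(bilinear_curve(2, 10, 0.03))
  expect_lt(abs(f$toe_modulus_MPa - 2) / 2, 1e-6)
  expect_lt(abs(f$linear_modulus_MPa - 10) / 10, 1e-6)
  expect_lt(abs(f$transition_strain - 0.03) / 0.03, 1e-6)
  expect_equal(f$max_strain, 0.06)
  # transition strictly between samples
  f2 <- bilinear_fit(bilinear_curve(1.5, 12, 0.0317, n = 57))
  expect_lt(abs(f2$transition_strain - 0.0317) / 0.0317, 1e-6)
  # the two-segment SSE never exceeds the single-line SSE
  set.seed(5)
  for (i in 1:10) {
    x <- sort(runif(30, 0, 0.08))
    y <- runif(30)
    fit <- bilinear_fit(data.frame(strain = x, stress_MPa = y))
    line_sse <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
    expect_lte(fit$sse, line_sse * (1 + 1e-9))
  }
})

test_that("a straight line yields equal slopes flagged as indeterminate", {
  x <- seq(0, 0.06, length.out = 40)
  f <- bilinear_fit(data.frame(strain = x, stress_MPa = 3 * x + 0.001))
  expect_equal(f$toe_modulus_MPa, f$linear_modulus_MPa, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
  expect_true(f$boundary_indeterminate)
})

test_that("non-monotone strain is rejected", {
  expect_error(
    bilinear_fit(data.frame(strain = c(0, 0.01, 0.005, 0.02, 0.03, 0.04,
                                       0.05, 0.06),
                            stress_MPa = 1:8)),
    "non-monotone"
  )
})

test_that("zero-noise generator output round-trips through the full chain", {
  geo <- disc_geometry(417, 5)
  grid <- expand.grid(toe = c(1, 3), lin = c(8, 25), tr = c(0.02, 0.04))
  for (i in seq_len(nrow(grid))) {
    rec <- generate_compression_test(grid$toe[i], grid$lin[i], grid$tr[i], geo)
    res <- analyze_disc_compression(rec, geo)
    b <- res$bilinear
    expect_lt(abs(b$toe_modulus_MPa - grid$toe[i]) / grid$toe[i], 1e-6)
    expect_lt(abs(b$linear_modulus_MPa - grid$lin[i]) / grid$lin[i], 1e-6)
    expect_lt(abs(b$transition_strain - grid$tr[i]) / grid$tr[i], 1e-6)
  }
})

test_that("creep strain matches the generator's exponential law", {
  geo <- disc_geometry(417, 5)
  rec <- generate_compression_test(2, 10, 0.03, geo, creep_asymptote = 0.05,
                                   creep_tau_s = 600)
  seg <- segment_cycles(rec)
  cr <- creep_strain(seg$creep, geo)
  expect_equal(cr$creep_strain, 0.05 * (1 - exp(-3600 / 600)),
               tolerance = 1e-6)
  # homogeneity: doubling height halves creep strain (same displacements)
  cr2 <- creep_strain(seg$creep, disc_geometry(417, 10))
  expect_equal(cr2$creep_strain, cr$creep_strain / 2, tolerance = 1e-12)
  # a flat hold accumulates nothing
  flat <- data.frame(time_s = 0:100, displacement_mm = rep(-0.5, 101))
  expect_equal(creep_strain(flat, geo)$creep_strain, 0)
})

test_that("scaling force and area together leaves all moduli unchanged", {
  geo <- disc_geometry(417, 5)
  rec <- generate_compression_test(2, 10, 0.03, geo)
  b1 <- analyze_disc_compression(rec, geo)$bilinear
  rec2 <- rec
  rec2$force_N <- rec$force_N * 3
  b2 <- analyze_disc_compression(rec2, disc_geometry(417 * 3, 5),
                                 peak_load_N = -300, low_load_N = -1.5)$bilinear
  expect_equal(b2$toe_modulus_MPa, b1$toe_modulus_MPa, tolerance = 1e-9)
  expect_equal(b2$linear_modulus_MPa, b1$linear_modulus_MPa, tolerance = 1e-9)
})
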