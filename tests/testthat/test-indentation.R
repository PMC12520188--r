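test_that("forward creep is monotone and reaches the Hertz equilibrium", {
  set.seed(77)
  times <- c(seq(0, 900, by = 5), 1e6)  # far tail probes d(Inf)
  for (i in 1:25) {
    ec <- runif(1, 0.1, 2)
    p <- biphasic_params(ec, ec * runif(1, 1.5, 30),
                         10^runif(1, -4, -2), poisson = runif(1, 0, 0.45))
    d <- hbc_forward(p, 0.1, 1, times)
    expect_true(all(diff(d) >= -1e-12))
    d_eq <- hertz_d_eq(p$e_c_MPa, 0.1, 1, p$poisson)
    expect_lt(abs(d[length(d)] - d_eq) / d_eq, 1e-6)
    # instantaneous response carries the solid load fraction e_c/e_t
    expect_lt(abs(d[1] - d_eq * (p$e_c_MPa / p$e_t_MPa)^(2 / 3)) / d_eq, 1e-9)
  }
})

test_that("the closed-form equilibrium example evaluates correctly", {
  p <- biphasic_params(1, 10, 1e-3)
  d <- hbc_forward(p, 0.1, 1, c(0, 1e7))
  expect_equal(d[2], 0.075^(2 / 3), tolerance = 1e-6)
})

test_that("no-pressurization limit: e_t -> e_c gives constant displacement", {
  p <- biphasic_params(1, 1 + 1e-9, 1e-3)
  d <- hbc_forward(p, 0.1, 1, seq(0, 900, by = 10))
  expect_lt(diff(range(d)) / mean(d), 1e-6)
  expect_equal(mean(d), hertz_d_eq(1, 0.1, 1), tolerance = 1e-6)
})

test_that("time-permeability scaling leaves the displacement series invariant", {
  times <- seq(0, 900, by = 5)
  p1 <- biphasic_params(0.5, 5, 1e-3)
  p2 <- biphasic_params(0.5, 5, 1e-2)
  d1 <- hbc_forward(p1, 0.1, 1, times)
  d2 <- hbc_forward(p2, 0.1, 1, times / 10)
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("parameter constraints are enforced", {
  expect_error(biphasic_params(2, 1, 1e-3), "tensile modulus must exceed")
  expect_error(biphasic_params(1, 2, -1e-3), "k_perm")
  expect_error(biphasic_params(1, 2, 1e-3, poisson = 0.6), "poisson")
})

test_that("noiseless creep records round-trip through the inverse fit", {
  proto <- acquisition_protocols()
  grid <- expand.grid(ec = c(0.2, 0.8), ratio = c(4, 15), k = c(3e-4, 3e-3))
  for (i in seq_len(nrow(grid))) {
    p <- biphasic_params(grid$ec[i], grid$ec[i] * grid$ratio[i], grid$k[i])
    rec <- generate_indentation_creep(p, proto)
    fit <- hbc_fit(rec)
    expect_false(fit$excluded)
    expect_lt(abs(fit$params$e_c_MPa - p$e_c_MPa) / p$e_c_MPa, 0.01)
    expect_lt(abs(fit$params$e_t_MPa - p$e_t_MPa) / p$e_t_MPa, 0.01)
    expect_lt(abs(fit$params$k_perm - p$k_perm) / p$k_perm, 0.01)
  }
})

test_that("a step artifact degrades r2 below the exclusion threshold", {
  p <- biphasic_params(0.5, 5, 1e-3)
  rec <- generate_indentation_creep(p)
  d <- rec$displacement_mm
  d[seq(length(d) %/% 2, length(d))] <-
    d[seq(length(d) %/% 2, length(d))] + 0.3  # gross slip mid-test
  bad <- indentation_record(rec$time_s, d, rec$load_N, rec$radius_mm)
  fit <- hbc_fit(bad)
  expect_true(fit$excluded)
  expect_lt(fit$r2, 0.95)
})

test_that("the exclusion flag flips exactly at the configured r2 threshold", {
  p <- biphasic_params(0.5, 5, 1e-3)
  rec <- generate_indentation_creep(p, noise_sd = 0.005, seed = 4)
  fit <- hbc_fit(rec)
  expect_false(fit$excluded)
  just_above <- hbc_fit(rec, r2_threshold = fit$r2 - 1e-9)
  just_below <- hbc_fit(rec, r2_threshold = fit$r2 + 1e-9)
  expect_false(just_above$excluded)
  expect_true(just_below$excluded)
})

test_that("joint aggregation averages non-excluded points and normalizes to control", {
  fits <- data.frame(
    animal = "A01",
    level = rep(c("C3-C4", "C2-C3"), each = 6),
    e_c_MPa = c(rep(0.8, 6), rep(0.4, 6)),
    e_t_MPa = c(rep(8, 6), rep(4, 6)),
    k_perm = c(rep(1e-3, 6), rep(3e-3, 6)),
    excluded = FALSE
  )
  fits$excluded[7] <- TRUE  # one treated point dropped by the r2 rule
  out <- aggregate_facet(fits, control_level = "C3-C4")
  ctrl <- out[out$level == "C3-C4", ]
  trt <- out[out$level == "C2-C3", ]
  expect_equal(ctrl$n_points_used, 6)
  expect_equal(trt$n_points_used, 5)
  expect_equal(unlist(ctrl[c("e_c_MPa_norm", "e_t_MPa_norm", "k_perm_norm")]),
               c(e_c_MPa_norm = 1, e_t_MPa_norm = 1, k_perm_norm = 1))
  expect_equal(trt$e_c_MPa_norm, 0.5)
  expect_equal(trt$k_perm_norm, 3)
})

test_that("a missing control joint skips normalization with a warning", {
  fits <- data.frame(animal = "A02", level = "C2-C3",
                     e_c_MPa = 0.4, e_t_MPa = 4, k_perm = 2e-3,
                     excluded = FALSE)
  expect_warning(out <- aggregate_facet(fits), "control level")
  expect_true(is.na(out$e_c_MPa_norm))
})
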