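test_that("noiseless decay and saturation limits match the closed forms", {
  sig <- generate_t2_decay(50, 100, 0)
  expect_equal(sig$intensity[1], 100 * exp(-13.6 / 50), tolerance = 1e-12)
  slow <- generate_t2_decay(1e9, 100, 0)
  expect_true(all(abs(slow$intensity - 100) < 1e-4))
})

test_that("pure-noise magnitudes have the Rayleigh mean", {
  # s0 -> 0 limit: magnitude of complex noise with per-channel SD 2
  proto <- acquisition_protocols(te_ms = seq(10, 20000, length.out = 2000))
  sig <- generate_t2_decay(t2_ms = 1, s0 = 1e-9, noise_sd = 2,
                           protocols = proto, seed = 21)
  expect_equal(mean(sig$intensity), 2 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("generators are reproducible under a fixed seed", {
  a <- generate_t2_decay(40, 100, 5, seed = 3)
  b <- generate_t2_decay(40, 100, 5, seed = 3)
  c <- generate_t2_decay(40, 100, 5, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))

  p <- biphasic_params(0.5, 5, 1e-3)
  r1 <- generate_indentation_creep(p, noise_sd = 0.002, seed = 6)
  r2 <- generate_indentation_creep(p, noise_sd = 0.002, seed = 6)
  expect_identical(r1, r2)
  # noiseless record equals the forward model exactly
  r0 <- generate_indentation_creep(p)
  expect_equal(r0$displacement_mm,
               hbc_forward(p, 0.1, 1, r0$time_s), tolerance = 1e-12)

  d <- cohort_design(6, seed = 10)
  expect_identical(generate_cohort(d), generate_cohort(d))
  d2 <- cohort_design(6, seed = 11)
  expect_false(identical(generate_cohort(d), generate_cohort(d2)))
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_t2_decay(40, 100, 5, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("the degenerate no-effect design yields constant outcomes", {
  d <- cohort_design(
    8, effect_map = zero_effect_slopes(default_effect_map()),
    noise_sd_map = default_noise_sd_map() * 0, seed = 5
  )
  tab <- generate_cohort(d)
  for (nm in names(default_effect_map())) {
    expect_equal(diff(range(tab[[nm]])), 0, info = nm)
  }
})

test_that("generated cohorts carry the assumed severity-driven structure", {
  tab <- generate_cohort(cohort_design(50, seed = 42))
  expect_equal(nrow(tab), 150)
  expect_true(all(tab$.severity >= 0 & tab$.severity <= 1))
  expect_true(all(tab$treatment[tab$level == "C3-C4"] == "control"))
  # each animal gets both doses on its treated levels
  doses <- tapply(tab$treatment[tab$treatment != "control"],
                  tab$animal[tab$treatment != "control"],
                  function(x) sort(x))
  expect_true(all(vapply(doses, function(x) identical(x, c("2U", "5U")),
                         logical(1))))
  # severity drives the signs the analysis assumes
  expect_lt(cor(tab$.severity, tab$np_t2_ms), -0.8)
  expect_gt(cor(tab$.severity, tab$toe_modulus_MPa), 0.8)
  expect_gt(cor(tab$.severity, tab$linear_modulus_MPa), 0.8)
  expect_lt(cor(tab$.severity, tab$facet_Et), -0.5)
  expect_gt(cor(tab$.severity, tab$facet_k), 0.5)
  expect_gt(cor(tab$.severity, tab$disc_histology_score), 0.5)
  # resorption is more likely in severe discs
  expect_gt(mean(tab$.severity[tab$endplate_resorption]),
            mean(tab$.severity[!tab$endplate_resorption]))
})

test_that("invalid designs are rejected", {
  expect_error(cohort_design(0), "n_animals")
  expect_error(cohort_design(5, severity_treated = c(0.5, 1.5)),
               "severity ranges")
  expect_error(cohort_design(5, noise_sd_map = -default_noise_sd_map()),
               "noise SDs")
})

test_that("traces and cohorts survive a text round trip", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp, paste0(tmp, c(".csv", ".csv.json")))), add = TRUE)
  rec <- generate_indentation_creep(biphasic_params(0.5, 5, 1e-3),
                                    noise_sd = 0.001, seed = 2)
  df <- data.frame(time_s = rec$time_s, displacement_mm = rec$displacement_mm)
  write_trace(df, tmp, header = c("units: s, mm", "load_N: 0.1 (magnitude)"))
  back <- read_trace(tmp)
  expect_equal(back$displacement_mm, df$displacement_mm, tolerance = 1e-12)

  tab <- generate_cohort(cohort_design(3, seed = 8))
  csv <- paste0(tmp, ".csv")
  write_cohort(tab, csv, settings = list(seed = 8, n_animals = 3))
  back_tab <- read_cohort(csv)
  expect_equal(back_tab$np_t2_ms, tab$np_t2_ms, tolerance = 1e-10)
  expect_true(file.exists(paste0(csv, ".json")))
  side <- jsonlite::read_json(paste0(csv, ".json"))
  expect_equal(side$seed, 8)
})
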