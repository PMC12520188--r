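#' Acquisition and testing protocols
#'
#' Bundles the imaging and mechanical-testing protocol parameters used by the
#' synthetic-data generators and, where relevant, by the fitting routines.
#' Defaults describe a cervical-spine structure-function study: a 25-echo CPMG
#' T2-mapping sequence (TE = 13.6, 27.2, ..., 340 ms), a two-flip-angle
#' spoiled-gradient T1 acquisition (TR = 15 ms, flip angles 5 and 26 degrees),
#' 20 compression cycles from -0.5 N to -100 N followed by a one-hour creep
#' hold, and spherical-indenter creep (2 mm diameter, -0.1 N, 15 minutes).
#'
#' Units are fixed package-wide: N, mm, MPa, seconds (echo times and relaxation
#' times in ms); hydraulic permeability in mm^4/(N s).
#'
#' @param te_ms echo times in ms, strictly increasing and positive.
#' @param tr_t1_ms repetition time of the T1 acquisition, ms.
#' @param flip_angles_deg two distinct flip angles in degrees, each in (0, 90].
#' @param compression_cycles number of load-unload compression cycles.
#' @param compression_load_range_N length-2 numeric, low and peak compressive
#'   loads in N (compression negative).
#' @param creep_hold_s duration of the compressive creep hold, s.
#' @param indent_load_N indentation creep load, N (compression negative).
#' @param indenter_radius_mm spherical indenter radius, mm.
#' @param indent_duration_s indentation creep duration, s.
#' @return An object of class `acquisition_protocols` (a validated list).
#' @export
acquisition_protocols <- function(te_ms = 13.6 * (1:25),
                                  tr_t1_ms = 15,
                                  flip_angles_deg = c(5, 26),
                                  compression_cycles = 20L,
                                  compression_load_range_N = c(-0.5, -100),
                                  creep_hold_s = 3600,
                                  indent_load_N = -0.1,
                                  indenter_radius_mm = 1.0,
                                  indent_duration_s = 900) {
  if (length(te_ms) < 2L || any(!is.finite(te_ms)) || any(te_ms <= 0) ||
      any(diff(te_ms) <= 0)) {
    stop_input("`te_ms` must be strictly increasing positive echo times")
  }
  assert_scalar_pos(tr_t1_ms, "tr_t1_ms")
  if (length(flip_angles_deg) != 2L || anyDuplicated(flip_angles_deg) ||
      any(flip_angles_deg <= 0) || any(flip_angles_deg > 90)) {
    stop_input("`flip_angles_deg` must be two distinct angles in (0, 90]")
  }
  if (compression_cycles < 1L) stop_input("`compression_cycles` must be >= 1")
  if (length(compression_load_range_N) != 2L ||
      any(compression_load_range_N >= 0) ||
      abs(compression_load_range_N[1]) >= abs(compression_load_range_N[2])) {
    stop_input("`compression_load_range_N` must be c(low, peak) compressive (negative), |low| < |peak|")
  }
  assert_scalar_pos(creep_hold_s, "creep_hold_s")
  if (!is.finite(indent_load_N) || indent_load_N == 0) {
    stop_input("`indent_load_N` must be a nonzero load")
  }
  assert_scalar_pos(indenter_radius_mm, "indenter_radius_mm")
  assert_scalar_pos(indent_duration_s, "indent_duration_s")
  structure(
    list(
      te_ms = as.numeric(te_ms),
      tr_t1_ms = tr_t1_ms,
      flip_angles_deg = as.numeric(flip_angles_deg),
      compression_cycles = as.integer(compression_cycles),
      compression_load_range_N = as.numeric(compression_load_range_N),
      creep_hold_s = creep_hold_s,
      indent_load_N = indent_load_N,
      indenter_radius_mm = indenter_radius_mm,
      indent_duration_s = indent_duration_s
    ),
    class = "acquisition_protocols"
  )
}

#' Default effect map linking latent severity to outcome means
#'
#' Each element is `c(intercept, slope)` on the outcome's own scale, giving the
#' noiseless outcome mean as `intercept + slope * s` for latent severity
#' `s` in \[0, 1\]. The trans-endplate diffusion outcome `pct_t1_reduction` is
#' special-cased: its slope multiplies the disc's (noiseless) NP T2 in ms, and
#' a third coefficient `elevation` is added for discs with endplate resorption
#' or severe degeneration (observed NP T2 < 40 ms), emulating enhanced
#' transport through breached or severely degenerate boundaries.
#'
#' Default magnitudes emulate the degeneration spectrum of a chondroitinase
#' large-animal model: NP T2 falling from ~75 ms (healthy) to ~30 ms (severe),
#' disc compressive moduli stiffening several-fold, facet cartilage moduli
#' softening and permeability rising several-fold, histology score rising.
#'
#' @return Named list of numeric coefficient vectors.
#' @export
default_effect_map <- function() {
  list(
    np_t2_ms              = c(intercept = 75,   slope = -45),
    dhi_normalized        = c(intercept = 1.0,  slope = -0.32),
    disc_histology_score  = c(intercept = 4,    slope = 10),
    toe_modulus_MPa       = c(intercept = 2,    slope = 5),
    linear_modulus_MPa    = c(intercept = 8,    slope = 24),
    transition_strain     = c(intercept = 0.03, slope = 0),
    max_strain            = c(intercept = 0.32, slope = 0),
    creep_strain          = c(intercept = 0.05, slope = 0),
    facet_Ec              = c(intercept = 1.0,  slope = -0.6),
    facet_Et              = c(intercept = 1.0,  slope = -0.6),
    facet_k               = c(intercept = 1.0,  slope = 3.3),
    facet_oarsi_score     = c(intercept = 3,    slope = 5),
    ep_bvtv               = c(intercept = 0.55, slope = 0.10),
    ep_tbn                = c(intercept = 2.0,  slope = 0.5),
    ep_tbsp               = c(intercept = 0.45, slope = -0.10),
    pct_t1_reduction      = c(intercept = 5, slope = 0.5, elevation = 25)
  )
}

#' Default per-outcome Gaussian noise standard deviations
#' @return Named numeric vector, same names as [default_effect_map()].
#' @export
default_noise_sd_map <- function() {
  c(
    np_t2_ms = 6, dhi_normalized = 0.05, disc_histology_score = 2,
    toe_modulus_MPa = 0.6, linear_modulus_MPa = 2.5,
    transition_strain = 0.004, max_strain = 0.04, creep_strain = 0.008,
    facet_Ec = 0.12, facet_Et = 0.12, facet_k = 0.45,
    facet_oarsi_score = 1.5, ep_bvtv = 0.04, ep_tbn = 0.2, ep_tbsp = 0.05,
    pct_t1_reduction = 4.5
  )
}

#' Cohort design for the synthetic-study generator
#'
#' Describes a cohort in which every animal contributes three cervical levels
#' (two treated, the middle one an untreated control) and a latent degeneration
#' severity per disc drives all outcomes through a linear effect map.
#'
#' @param n_animals number of animals (>= 1).
#' @param levels_per_animal spinal levels per animal; the middle level is the
#'   within-animal control (default 3: C2-C3, C3-C4 control, C4-C5).
#' @param severity_treated range of the Uniform severity distribution for
#'   treated levels (default `c(0.2, 1)`).
#' @param severity_control range for control levels (default `c(0, 0.15)`:
#'   controls show at most mild degenerative change).
#' @param effect_map per-outcome `c(intercept, slope)` coefficients, see
#'   [default_effect_map()].
#' @param noise_sd_map per-outcome Gaussian noise SDs (all >= 0).
#' @param resorption_logit `c(intercept, slope)` of the logistic model giving
#'   the probability of endplate resorption as a function of severity.
#' @param seed integer seed; fixing it fixes the whole generated cohort.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_animals,
                          levels_per_animal = 3L,
                          severity_treated = c(0.2, 1.0),
                          severity_control = c(0.0, 0.15),
                          effect_map = default_effect_map(),
                          noise_sd_map = default_noise_sd_map(),
                          resorption_logit = c(intercept = -4, slope = 5),
                          seed = NULL) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L ||
      !is.finite(n_animals) || n_animals < 1) {
    stop_input("invalid design: `n_animals` must be a positive count")
  }
  if (levels_per_animal < 2L) {
    stop_input("invalid design: `levels_per_animal` must be >= 2")
  }
  for (rng in list(severity_treated, severity_control)) {
    if (length(rng) != 2L || any(rng < 0) || any(rng > 1) || rng[1] > rng[2]) {
      stop_input("invalid design: severity ranges must lie in [0, 1]")
    }
  }
  if (!is.list(effect_map) || is.null(names(effect_map))) {
    stop_input("invalid design: `effect_map` must be a named list")
  }
  if (any(noise_sd_map < 0)) {
    stop_input("invalid design: all noise SDs must be >= 0")
  }
  missing_sd <- setdiff(names(effect_map), names(noise_sd_map))
  if (length(missing_sd)) {
    stop_input("invalid design: no noise SD for outcome(s): %s",
               paste(missing_sd, collapse = ", "))
  }
  if (length(resorption_logit) != 2L || any(!is.finite(resorption_logit))) {
    stop_input("invalid design: `resorption_logit` must be c(intercept, slope)")
  }
  structure(
    list(
      n_animals = as.integer(n_animals),
      levels_per_animal = as.integer(levels_per_animal),
      severity_treated = severity_treated,
      severity_control = severity_control,
      effect_map = effect_map,
      noise_sd_map = noise_sd_map,
      resorption_logit = resorption_logit,
      seed = seed
    ),
    class = "cohort_design"
  )
}

#' Set every effect-map slope (and elevation) to zero
#'
#' Convenience for the degenerate no-effect design in which all outcomes are
#' constant across records.
#'
#' @param effect_map an effect map as from [default_effect_map()].
#' @return The effect map with all coefficients beyond the intercept zeroed.
#' @export
zero_effect_slopes <- function(effect_map) {
  lapply(effect_map, function(co) {
    co[-1] <- 0
    co
  })
}
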