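#' Simulate a multi-echo magnitude decay with Rician noise
#'
#' Generates the magnitude of `s0 exp(-TE/T2)` corrupted by complex Gaussian
#' noise with per-channel SD `noise_sd`, i.e. Rician-distributed magnitudes.
#' Noise is added on the two channels, not to the magnitude, so the noise
#' floor that the corrected T2 estimator must absorb is produced honestly.
#'
#' @param t2_ms true T2, ms.
#' @param s0 true amplitude.
#' @param noise_sd per-channel Gaussian noise SD (0 for a noiseless decay).
#' @param protocols an [acquisition_protocols()]; supplies the TE schedule.
#' @param seed optional integer seed.
#' @return A [relaxation_signal()].
#' @export
generate_t2_decay <- function(t2_ms, s0, noise_sd = 0,
                              protocols = acquisition_protocols(),
                              seed = NULL) {
  assert_scalar_pos(t2_ms, "t2_ms")
  assert_scalar_pos(s0, "s0")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  te <- protocols$te_ms
  clean <- s0 * exp(-te / t2_ms)
  mag <- with_seed(seed, {
    if (noise_sd > 0) {
      sqrt((clean + stats::rnorm(length(te), 0, noise_sd))^2 +
             stats::rnorm(length(te), 0, noise_sd)^2)
    } else {
      clean
    }
  })
  relaxation_signal(te, mag)
}

#' Simulate a two-flip-angle spoiled-gradient signal pair
#'
#' Evaluates `m0 sin(a) (1 - E1) / (1 - E1 cos(a))` with
#' `E1 = exp(-TR/T1)` at each protocol flip angle and adds Gaussian noise.
#'
#' @param t1_ms true T1, ms.
#' @param m0 equilibrium magnetization scale.
#' @param protocols an [acquisition_protocols()]; supplies TR and the angles.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed optional integer seed.
#' @return A [vfa_signals()] set.
#' @export
generate_vfa_signals <- function(t1_ms, m0 = 1,
                                 protocols = acquisition_protocols(),
                                 noise_sd = 0, seed = NULL) {
  assert_scalar_pos(t1_ms, "t1_ms")
  assert_scalar_pos(m0, "m0")
  a_deg <- protocols$flip_angles_deg
  if (any(a_deg %% 180 == 0)) {
    stop_input("invalid protocol: flip angle of 0 or 180 degrees")
  }
  a <- a_deg * pi / 180
  e1 <- exp(-protocols$tr_t1_ms / t1_ms)
  s <- m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
  s <- with_seed(seed, s + if (noise_sd > 0)
    stats::rnorm(length(s), 0, noise_sd) else 0)
  vfa_signals(protocols$tr_t1_ms, a_deg, s)
}

# Invert the bilinear stress-strain law: strain at a given stress.
bilinear_strain_at <- function(stress, toe, linear, transition) {
  sigma_t <- toe * transition
  ifelse(stress <= sigma_t, stress / toe,
         transition + (stress - sigma_t) / linear)
}

#' Simulate a cyclic compression + creep load-displacement record
#'
#' Synthesizes the machine output of a motion-segment compression test:
#' `compression_cycles` triangular load-unload cycles between the protocol
#' load setpoints, with displacement tracing the bilinear stress-strain law
#' (toe modulus below the transition strain, linear modulus above) through
#' the disc geometry, followed by a creep hold at peak load during which
#' strain approaches `creep_asymptote` exponentially with time constant
#' `creep_tau_s`. Compression is negative in force and displacement.
#' Gaussian noise is added to displacement.
#'
#' @param toe_modulus_MPa,linear_modulus_MPa,transition_strain generating
#'   bilinear law (moduli > 0, transition in (0, 1)).
#' @param geometry a [disc_geometry()].
#' @param protocols an [acquisition_protocols()].
#' @param creep_asymptote asymptotic additional creep strain.
#' @param creep_tau_s creep time constant, s.
#' @param noise_sd displacement noise SD, mm.
#' @param points_per_ramp samples per loading (and unloading) ramp.
#' @param ramp_duration_s duration of each ramp, s.
#' @param creep_dt_s creep-hold sampling interval, s.
#' @param seed optional integer seed.
#' @return A [load_displacement_record()].
#' @export
generate_compression_test <- function(toe_modulus_MPa, linear_modulus_MPa,
                                      transition_strain, geometry,
                                      protocols = acquisition_protocols(),
                                      creep_asymptote = 0.05,
                                      creep_tau_s = 600,
                                      noise_sd = 0,
                                      points_per_ramp = 100L,
                                      ramp_duration_s = 5,
                                      creep_dt_s = 1,
                                      seed = NULL) {
  assert_scalar_pos(toe_modulus_MPa, "toe_modulus_MPa")
  assert_scalar_pos(linear_modulus_MPa, "linear_modulus_MPa")
  if (transition_strain <= 0 || transition_strain >= 1) {
    stop_input("`transition_strain` must lie in (0, 1)")
  }
  stopifnot(inherits(geometry, "disc_geometry"))
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")

  f_low <- abs(protocols$compression_load_range_N[1])
  f_peak <- abs(protocols$compression_load_range_N[2])
  n_cyc <- protocols$compression_cycles
  area <- geometry$area_mm2
  h <- geometry$height_mm

  up <- seq(f_low, f_peak, length.out = points_per_ramp)
  down <- rev(up)[-1]
  force_mag <- c(rep(c(up, down[-length(down)]), n_cyc - 1), up)
  t_ramp <- ramp_duration_s / (points_per_ramp - 1)
  time <- seq_along(force_mag) * t_ramp

  strain <- bilinear_strain_at(force_mag / area, toe_modulus_MPa,
                               linear_modulus_MPa, transition_strain)

  # creep hold at peak load
  t_hold <- seq(creep_dt_s, protocols$creep_hold_s, by = creep_dt_s)
  strain_peak <- strain[length(strain)]
  strain_hold <- strain_peak + creep_asymptote * (1 - exp(-t_hold / creep_tau_s))

  time <- c(time, time[length(time)] + t_hold)
  force <- -c(force_mag, rep(f_peak, length(t_hold)))
  disp <- -c(strain, strain_hold) * h
  disp <- with_seed(seed, disp + if (noise_sd > 0)
    stats::rnorm(length(disp), 0, noise_sd) else 0)

  load_displacement_record(time, force, disp, metadata = list(
    generator = "bilinear+creep",
    toe_modulus_MPa = toe_modulus_MPa,
    linear_modulus_MPa = linear_modulus_MPa,
    transition_strain = transition_strain,
    creep_asymptote = creep_asymptote, creep_tau_s = creep_tau_s
  ))
}

#' Simulate a spherical-indenter biphasic creep record
#'
#' Evaluates [hbc_forward()] on a uniform time grid over the protocol's
#' indentation duration and adds Gaussian displacement noise.
#'
#' @param params a [biphasic_params()].
#' @param protocols an [acquisition_protocols()].
#' @param noise_sd displacement noise SD, mm.
#' @param dt_s sampling interval, s.
#' @param seed optional integer seed.
#' @return An [indentation_record()].
#' @export
generate_indentation_creep <- function(params,
                                       protocols = acquisition_protocols(),
                                       noise_sd = 0, dt_s = 5, seed = NULL) {
  stopifnot(inherits(params, "biphasic_params"))
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  times <- seq(0, protocols$indent_duration_s, by = dt_s)
  P <- abs(protocols$indent_load_N)
  R <- protocols$indenter_radius_mm
  d <- hbc_forward(params, P, R, times)
  d <- with_seed(seed, d + if (noise_sd > 0)
    stats::rnorm(length(d), 0, noise_sd) else 0)
  indentation_record(times, pmax(d, 0), load_N = P, radius_mm = R)
}

#' Simulate radiographic landmarks for one disc level
#'
#' Constructs the canonical landmark geometry — three parallel disc-height
#' chords (anterior, middle, posterior) and the long-axis endpoint pairs of
#' the two adjacent vertebrae — then applies a rigid rotation/translation and
#' optional Gaussian landmark jitter. By construction the noiseless disc
#' height index is `disc_height_mm / mean(vertebra_lengths_mm)`.
#'
#' @param disc_height_mm disc height (all three chords), mm.
#' @param vertebra_lengths_mm lengths of the cranial and caudal vertebral
#'   bodies, mm (length 2).
#' @param pose list with `angle_deg` and `offset` (length-2) giving the rigid
#'   motion applied to all points.
#' @param disc_width_mm anterior-posterior spread of the three chords, mm.
#' @param jitter_sd Gaussian landmark jitter SD, mm.
#' @param seed optional integer seed.
#' @return A [landmark_set()].
#' @export
generate_radiograph_landmarks <- function(disc_height_mm,
                                          vertebra_lengths_mm = c(25, 25),
                                          pose = list(angle_deg = 0,
                                                      offset = c(0, 0)),
                                          disc_width_mm = 15,
                                          jitter_sd = 0, seed = NULL) {
  assert_scalar_pos(disc_height_mm, "disc_height_mm")
  if (length(vertebra_lengths_mm) != 2L || any(vertebra_lengths_mm <= 0)) {
    stop_input("`vertebra_lengths_mm` must be two positive lengths")
  }
  half_h <- disc_height_mm / 2
  xs <- c(-1, 0, 1) * disc_width_mm / 2
  chords <- lapply(xs, function(x) rbind(c(x, -half_h), c(x, half_h)))
  gap <- 1
  cran <- rbind(c(0, half_h + gap),
                c(0, half_h + gap + vertebra_lengths_mm[1]))
  caud <- rbind(c(0, -half_h - gap),
                c(0, -half_h - gap - vertebra_lengths_mm[2]))

  th <- pose$angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xform <- function(m) {
    out <- t(rot %*% t(m)) + matrix(pose$offset, nrow(m), 2, byrow = TRUE)
    out
  }
  pts <- lapply(c(chords, list(cran, caud)), xform)
  pts <- with_seed(seed, {
    if (jitter_sd > 0) {
      lapply(pts, function(m) m + matrix(stats::rnorm(4, 0, jitter_sd), 2, 2))
    } else pts
  })
  landmark_set(pts[1:3], pts[[4]], pts[[5]])
}

#' Generate a synthetic degeneration cohort
#'
#' Draws one latent degeneration severity `s` in \[0, 1\] per disc (treated
#' levels from `severity_treated`, the middle control level from
#' `severity_control`), then maps `s` to every derived outcome through the
#' design's linear effect map plus Gaussian noise. The severity jointly
#' drives lower NP T2, stiffer disc compressive moduli, softer and more
#' permeable facet cartilage and higher histology score. Endplate resorption
#' occurs with logistic probability in `s`; the trans-endplate diffusion
#' metric increases with NP T2 among intact, non-severe discs but is elevated
#' when the resorption flag is set or degeneration is severe (observed
#' NP T2 < 40 ms). The latent severity is retained as hidden column
#' `.severity`; the table is reproducible under the design seed.
#'
#' @param design a [cohort_design()].
#' @return data.frame (one row per animal x level) with identifier columns
#'   (`specimen_id`, `animal`, `level`, `treatment`), `endplate_resorption`,
#'   every effect-map outcome, `degeneration_grade` and `.severity`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_animals
  lv <- design$levels_per_animal
  ctrl_idx <- ceiling(lv / 2)
  level_labels <- if (lv == 3L) c("C2-C3", "C3-C4", "C4-C5") else
    paste0("L", seq_len(lv))

  with_seed(design$seed, {
    rows <- vector("list", n)
    for (a in seq_len(n)) {
      is_ctrl <- seq_len(lv) == ctrl_idx
      s <- numeric(lv)
      s[is_ctrl] <- stats::runif(sum(is_ctrl), design$severity_control[1],
                                 design$severity_control[2])
      s[!is_ctrl] <- stats::runif(sum(!is_ctrl), design$severity_treated[1],
                                  design$severity_treated[2])
      doses <- sample(rep(c("2U", "5U"), length.out = sum(!is_ctrl)))
      treatment <- character(lv)
      treatment[is_ctrl] <- "control"
      treatment[!is_ctrl] <- doses
      rows[[a]] <- data.frame(
        specimen_id = sprintf("A%02d_%s", a, level_labels),
        animal = sprintf("A%02d", a),
        level = level_labels, treatment = treatment,
        .severity = s, stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    s <- tab$.severity

    em <- design$effect_map
    sd_map <- design$noise_sd_map
    noisy <- function(mu, sd) mu + if (sd > 0)
      stats::rnorm(length(mu), 0, sd) else 0

    # resorption flag: logistic in severity
    p_res <- stats::plogis(design$resorption_logit[1] +
                             design$resorption_logit[2] * s)
    tab$endplate_resorption <- stats::runif(length(s)) < p_res

    diffusion_co <- em$pct_t1_reduction
    plain <- setdiff(names(em), "pct_t1_reduction")
    floors <- c(np_t2_ms = 1, toe_modulus_MPa = 0.01,
                linear_modulus_MPa = 0.01, transition_strain = 1e-4,
                max_strain = 1e-4, creep_strain = 0, facet_Ec = 0.01,
                facet_Et = 0.01, facet_k = 0.01, dhi_normalized = 0.01,
                disc_histology_score = 0, facet_oarsi_score = 0,
                ep_bvtv = 0.01, ep_tbn = 0.01, ep_tbsp = 0.01)
    for (nm in plain) {
      co <- em[[nm]]
      v <- noisy(co[1] + co[2] * s, sd_map[[nm]])
      if (nm %in% names(floors)) v <- pmax(v, floors[[nm]])
      tab[[nm]] <- v
    }

    if (!is.null(diffusion_co)) {
      t2_true <- em$np_t2_ms[1] + em$np_t2_ms[2] * s
      elevated <- tab$endplate_resorption | tab$np_t2_ms < 40
      elev_co <- if (length(diffusion_co) >= 3) diffusion_co[3] else 0
      mu <- diffusion_co[1] + diffusion_co[2] * t2_true +
        ifelse(elevated, elev_co, 0)
      tab$pct_t1_reduction <- noisy(mu, sd_map[["pct_t1_reduction"]])
    }

    rownames(tab) <- NULL
    stratify_by_t2(tab)
  })
}
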