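#' Disc geometry from MRI
#'
#' @param area_mm2 axial cross-sectional disc area, mm^2.
#' @param height_mm disc height, mm.
#' @return Object of class `disc_geometry`.
#' @export
disc_geometry <- function(area_mm2, height_mm) {
  assert_scalar_pos(area_mm2, "area_mm2")
  assert_scalar_pos(height_mm, "height_mm")
  structure(list(area_mm2 = area_mm2, height_mm = height_mm),
            class = "disc_geometry")
}

#' Disc area from a binary axial MRI mask
#'
#' Area = (number of in-disc pixels) x (in-plane resolution)^2.
#'
#' @param axial_mask logical (or 0/1) matrix marking in-disc pixels.
#' @param in_plane_resolution_mm pixel edge length, mm.
#' @return area in mm^2.
#' @export
disc_area_from_mask <- function(axial_mask, in_plane_resolution_mm) {
  assert_scalar_pos(in_plane_resolution_mm, "in_plane_resolution_mm")
  n <- sum(as.logical(axial_mask), na.rm = TRUE)
  if (n == 0) stop_input("empty mask: zero disc area")
  n * in_plane_resolution_mm^2
}

#' Disc height from a binary mid-sagittal MRI mask
#'
#' Height = (mid-sagittal disc area) / (anterior-posterior width), where the
#' AP width spans the occupied pixel columns: `(max col - min col + 1) x
#' resolution`. This is the mean disc height over the AP extent.
#'
#' @param sagittal_mask logical (or 0/1) matrix; columns run
#'   anterior-posterior.
#' @param in_plane_resolution_mm pixel edge length, mm.
#' @return height in mm.
#' @export
disc_height_from_sagittal <- function(sagittal_mask, in_plane_resolution_mm) {
  assert_scalar_pos(in_plane_resolution_mm, "in_plane_resolution_mm")
  m <- as.matrix(sagittal_mask)
  occupied_cols <- which(colSums(m != 0, na.rm = TRUE) > 0)
  if (!length(occupied_cols)) stop_input("empty mask: no disc pixels")
  area <- sum(m != 0, na.rm = TRUE) * in_plane_resolution_mm^2
  width <- (max(occupied_cols) - min(occupied_cols) + 1) *
    in_plane_resolution_mm
  area / width
}

#' Load-displacement record from a motion-segment compression test
#'
#' Raw machine output: compression is negative in both force and
#' displacement. Time must be strictly increasing.
#'
#' @param time_s,force_N,displacement_mm equal-length numeric vectors.
#' @param metadata optional named list (specimen id, protocol, ...).
#' @return Object of class `load_displacement_record` (a data.frame with a
#'   `metadata` attribute).
#' @export
load_displacement_record <- function(time_s, force_N, displacement_mm,
                                     metadata = list()) {
  n <- length(time_s)
  if (length(force_N) != n || length(displacement_mm) != n) {
    stop_input("time, force and displacement must have equal lengths")
  }
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0)) {
    stop_input("`time_s` must be strictly increasing")
  }
  out <- data.frame(time_s = time_s, force_N = force_N,
                    displacement_mm = displacement_mm)
  attr(out, "metadata") <- metadata
  class(out) <- c("load_displacement_record", "data.frame")
  out
}

#' Normalize a load-displacement record to stress and strain
#'
#' Stress = |force| / area (MPa); strain = |displacement - reference| /
#' height. Compression is positive in both axes after normalization. By
#' default the displacement reference is the record's own zero (strain
#' referenced to the unloaded disc height); `rezero = "segment"` instead
#' re-zeroes to the first sample of the supplied segment.
#'
#' @param record a [load_displacement_record()] (or any segment of one).
#' @param geometry a [disc_geometry()].
#' @param rezero `"none"` (default) or `"segment"`.
#' @return Object of class `stress_strain_curve`: data.frame with `time_s`,
#'   `strain`, `stress_MPa`.
#' @export
normalize_stress_strain <- function(record, geometry,
                                    rezero = c("none", "segment")) {
  stopifnot(inherits(geometry, "disc_geometry"))
  rezero <- match.arg(rezero)
  if (!all(c("time_s", "force_N", "displacement_mm") %in% names(record))) {
    stop_input("record must have time_s, force_N, displacement_mm columns")
  }
  ref <- if (rezero == "segment") record$displacement_mm[1] else 0
  out <- data.frame(
    time_s = record$time_s,
    strain = abs(record$displacement_mm - ref) / geometry$height_mm,
    stress_MPa = abs(record$force_N) / geometry$area_mm2
  )
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' Segment a cyclic compression record into loading ramps and the creep hold
#'
#' Cycles are delimited by excursions of |force| above a hysteresis band
#' around the low-load setpoint (band half-width `hysteresis` x |low
#' setpoint|, default 20 %), so sensor noise smaller than the band cannot
#' split or merge cycles. Each excursion that reaches at least half the peak
#' setpoint counts as one cycle; its loading ramp runs from the excursion
#' start to the first sample attaining the excursion's peak force. A trailing
#' at-peak portion of the final excursion longer than `hold_min_s` is
#' returned as the creep segment.
#'
#' @param record a [load_displacement_record()].
#' @param n_cycles declared number of compression cycles (default 20).
#' @param low_load_N,peak_load_N protocol setpoints, N (compression
#'   negative).
#' @param hysteresis half-width of the low-load band as a fraction of
#'   |low_load_N|.
#' @param hold_min_s minimum duration for the trailing hold to count as the
#'   creep segment, s.
#' @return list with `cycles` (list of `n_cycles` loading-ramp data.frames),
#'   `creep` (data.frame or NULL), `n_detected`.
#' @export
segment_cycles <- function(record, n_cycles = 20L, low_load_N = -0.5,
                           peak_load_N = -100, hysteresis = 0.2,
                           hold_min_s = 10) {
  s <- abs(record$force_N)
  band_top <- abs(low_load_N) * (1 + hysteresis)
  above <- s > band_top
  if (!any(above)) {
    stop_input("segmentation error: expected %d cycles, found 0", n_cycles)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # keep excursions that actually load toward the peak setpoint
  runs <- runs[vapply(runs, function(i) {
    max(s[starts[i]:ends[i]]) >= 0.5 * abs(peak_load_N)
  }, logical(1))]
  n_found <- length(runs)
  if (n_found < n_cycles) {
    stop_input("segmentation error: expected %d cycles, found %d",
               n_cycles, n_found)
  }
  cycles <- vector("list", n_cycles)
  creep <- NULL
  for (ci in seq_len(n_cycles)) {
    i <- runs[ci]
    idx <- starts[i]:ends[i]
    peak <- max(s[idx])
    ramp_end <- idx[which(s[idx] >= 0.995 * peak)[1]]
    cycles[[ci]] <- record[starts[i]:ramp_end, , drop = FALSE]
    if (ci == n_cycles) {
      hold_idx <- ramp_end:ends[i]
      near_peak <- s[hold_idx] >= 0.95 * peak
      hold_idx <- hold_idx[near_peak]
      if (length(hold_idx) > 1 &&
          diff(range(record$time_s[hold_idx])) >= hold_min_s) {
        creep <- record[hold_idx, , drop = FALSE]
      }
    }
  }
  list(cycles = cycles, creep = creep, n_detected = n_found)
}

#' Continuous bilinear (toe/linear) fit of a stress-strain loading ramp
#'
#' Fits the continuous two-segment piecewise-linear model
#' `stress = a + toe * strain + (linear - toe) * max(strain - t, 0)` by least
#' squares. Conditional on the breakpoint `t` the model is linear, so the fit
#' searches every admissible interior sample position (at least `min_seg`
#' points per segment) exhaustively and then refines the breakpoint
#' continuously within the bracketing inter-sample intervals. The toe modulus
#' is the lower-strain slope, the linear modulus the upper-strain slope, and
#' the transition strain the breakpoint abscissa — under the continuity
#' constraint this is also the intersection of the two fitted lines.
#'
#' When the data are statistically indistinguishable from a single line the
#' two slopes agree and the transition is flagged `boundary_indeterminate`.
#'
#' @param curve a `stress_strain_curve` (or data.frame with `strain`,
#'   `stress_MPa`), strain non-decreasing along a monotone loading ramp.
#' @param min_seg minimum samples per segment (>= 3).
#' @return Object of class `bilinear_fit`: list with `toe_modulus_MPa`,
#'   `linear_modulus_MPa`, `transition_strain`, `max_strain`, `r2`,
#'   `n_points`, `sse`, `boundary_indeterminate`.
#' @export
bilinear_fit <- function(curve, min_seg = 3L) {
  if (!all(c("strain", "stress_MPa") %in% names(curve))) {
    stop_input("curve must have `strain` and `stress_MPa` columns")
  }
  x <- curve$strain
  y <- curve$stress_MPa
  # clean: collapse duplicate strains, then require monotone loading
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, match(x, unique(x)), mean))
    x <- unique(x)
  }
  if (any(diff(x) < 0)) {
    stop_input("non-monotone strain: not a single loading ramp")
  }
  n <- length(x)
  if (n < 8L) stop_input("at least 8 points are required for a bilinear fit")
  if (min_seg < 3L) stop_input("`min_seg` must be >= 3")

  hinge_sse <- function(cc) {
    X <- cbind(1, x, pmax(x - cc, 0))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  hinge_coef <- function(cc) stats::lm.fit(cbind(1, x, pmax(x - cc, 0)), y)

  ks <- seq.int(min_seg, n - min_seg + 1L)
  sse_k <- vapply(x[ks], hinge_sse, numeric(1))
  best_i <- which.min(sse_k)
  k <- ks[best_i]
  # continuous refinement in the two intervals bracketing the best grid point
  cand <- list(list(c = x[k], sse = sse_k[best_i]))
  lo <- x[max(k - 1L, 1L)]
  hi <- x[min(k + 1L, n)]
  for (iv in list(c(lo, x[k]), c(x[k], hi))) {
    if (diff(iv) > 0) {
      op <- stats::optimize(hinge_sse, interval = iv, tol = 1e-10)
      cand <- c(cand, list(list(c = op$minimum, sse = op$objective)))
    }
  }
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "sse"))]]
  cfit <- hinge_coef(best$c)
  b <- cfit$coefficients
  toe <- b[2]
  linear <- b[2] + b[3]
  sse <- sum(cfit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1

  # single-line reference: flags slope-indistinguishable (degenerate) inputs
  line_sse <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  indeterminate <- best_i %in% c(1L, length(ks)) ||
    line_sse <= sse * (1 + 1e-9) + 1e-300
  if (abs(b[3]) < 1e-10 * max(abs(toe), 1e-12)) indeterminate <- TRUE

  structure(
    list(toe_modulus_MPa = unname(toe), linear_modulus_MPa = unname(linear),
         transition_strain = unname(best$c), max_strain = max(x), r2 = r2,
         n_points = n, sse = sse, boundary_indeterminate = indeterminate),
    class = "bilinear_fit"
  )
}

#' Creep strain over a compressive hold
#'
#' Strain accumulated between the start and end of the constant-load hold:
#' `(|displacement_end| - |displacement_start|) / height`, positive in
#' compression.
#'
#' @param creep_segment data.frame with `time_s` and `displacement_mm`
#'   (e.g. the `creep` element of [segment_cycles()]).
#' @param geometry a [disc_geometry()].
#' @param min_duration_s shortest admissible hold, s.
#' @return list with `creep_strain` and `hold_duration_s`.
#' @export
creep_strain <- function(creep_segment, geometry, min_duration_s = 1) {
  stopifnot(inherits(geometry, "disc_geometry"))
  if (is.null(creep_segment) || nrow(creep_segment) < 2L) {
    stop_input("creep hold segment missing or too short")
  }
  dur <- diff(range(creep_segment$time_s))
  if (dur < min_duration_s) {
    stop_input("creep hold (%.3g s) shorter than the declared minimum (%.3g s)",
               dur, min_duration_s)
  }
  d <- abs(creep_segment$displacement_mm)
  list(creep_strain = (d[length(d)] - d[1]) / geometry$height_mm,
       hold_duration_s = dur)
}

#' Full disc-compression analysis of one record
#'
#' Convenience chain: segment the cycles, normalize the chosen loading ramp
#' (by default the 20th) to stress-strain, fit the bilinear model and compute
#' creep strain from the terminal hold.
#'
#' @param record a [load_displacement_record()].
#' @param geometry a [disc_geometry()].
#' @param cycle index of the loading ramp to fit.
#' @inheritParams segment_cycles
#' @return list with `bilinear` ([bilinear_fit()] result), `creep`
#'   ([creep_strain()] result or NULL), `n_cycles_detected`.
#' @export
analyze_disc_compression <- function(record, geometry, cycle = 20L,
                                     n_cycles = 20L, low_load_N = -0.5,
                                     peak_load_N = -100) {
  seg <- segment_cycles(record, n_cycles = n_cycles, low_load_N = low_load_N,
                        peak_load_N = peak_load_N)
  if (cycle < 1L || cycle > length(seg$cycles)) {
    stop_input("requested cycle %d outside the %d detected cycles",
               cycle, length(seg$cycles))
  }
  curve <- normalize_stress_strain(seg$cycles[[cycle]], geometry)
  fit <- bilinear_fit(curve)
  cr <- if (!is.null(seg$creep)) creep_strain(seg$creep, geometry) else NULL
  list(bilinear = fit, creep = cr, n_cycles_detected = seg$n_detected)
}
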