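# Shared fixtures and independent oracles, built in code at test time.

default_geometry <- function() disc_geometry(area_mm2 = 417, height_mm = 5)

# Exact bilinear stress-strain samples (no noise).
bilinear_curve <- function(toe, linear, transition, max_strain = 2 * transition,
                           n = 60) {
  x <- seq(0, max_strain, length.out = n)
  y <- ifelse(x <= transition, toe * x,
              toe * transition + linear * (x - transition))
  structure(data.frame(strain = x, stress_MPa = y),
            class = c("stress_strain_curve", "data.frame"))
}

# Hertz equilibrium indentation depth: independent closed form.
hertz_d_eq <- function(ec, load, radius, nu = 0) {
  (3 * load * (1 - nu^2) / (4 * ec * sqrt(radius)))^(2 / 3)
}

# Rigid motion of a landmark set (oracle side: applied from outside).
transform_landmarks <- function(lms, angle_deg, offset, scale = 1) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f <- function(m) scale * t(rot %*% t(m)) +
    matrix(offset, 2, 2, byrow = TRUE)
  landmark_set(lapply(lms$disc_chords, f), f(lms$cranial_vertebra),
               f(lms$caudal_vertebra))
}
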