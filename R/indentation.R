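#' Biphasic material parameters for facet cartilage
#'
#' Parameters of the Hertzian biphasic creep model: equilibrium compressive
#' (contact) modulus `e_c` (MPa), tensile modulus `e_t` (MPa, must exceed
#' `e_c` — tension-compression nonlinearity drives interstitial fluid
#' pressurization), hydraulic permeability `k` (mm^4/(N s)) and the solid
#' matrix Poisson ratio (default 0, the standard biphasic assumption).
#'
#' @param e_c_MPa equilibrium compressive modulus, MPa, > 0.
#' @param e_t_MPa tensile modulus, MPa, > `e_c_MPa`.
#' @param k_perm hydraulic permeability, mm^4/(N s), > 0.
#' @param poisson solid-matrix Poisson ratio in \[0, 0.5).
#' @return Object of class `biphasic_params`.
#' @export
biphasic_params <- function(e_c_MPa, e_t_MPa, k_perm, poisson = 0) {
  assert_scalar_pos(e_c_MPa, "e_c_MPa")
  assert_scalar_pos(e_t_MPa, "e_t_MPa")
  assert_scalar_pos(k_perm, "k_perm")
  if (e_t_MPa <= e_c_MPa) {
    stop_input("invalid params: tensile modulus must exceed compressive modulus")
  }
  if (poisson < 0 || poisson >= 0.5) {
    stop_input("invalid params: `poisson` must lie in [0, 0.5)")
  }
  structure(list(e_c_MPa = e_c_MPa, e_t_MPa = e_t_MPa, k_perm = k_perm,
                 poisson = poisson),
            class = "biphasic_params")
}

#' Spherical-indenter creep record
#'
#' @param time_s sampling times, increasing from 0.
#' @param displacement_mm non-negative indentation depths.
#' @param load_N creep load magnitude (a negative machine value is accepted
#'   and its magnitude used), default 0.1 N.
#' @param radius_mm indenter radius, default 1 mm (2 mm diameter sphere).
#' @param site optional label (e.g. "superior-2").
#' @return Object of class `indentation_record`.
#' @export
indentation_record <- function(time_s, displacement_mm, load_N = 0.1,
                               radius_mm = 1.0, site = NA_character_) {
  if (length(time_s) != length(displacement_mm)) {
    stop_input("time and displacement must have equal lengths")
  }
  if (time_s[1] < 0 || any(diff(time_s) <= 0)) {
    stop_input("`time_s` must increase from 0")
  }
  if (any(!is.finite(displacement_mm)) || any(displacement_mm < 0)) {
    stop_input("`displacement_mm` must be non-negative")
  }
  if (!is.finite(load_N) || load_N == 0) stop_input("`load_N` must be nonzero")
  assert_scalar_pos(radius_mm, "radius_mm")
  structure(list(time_s = as.numeric(time_s),
                 displacement_mm = as.numeric(displacement_mm),
                 load_N = abs(load_N), radius_mm = radius_mm, site = site),
            class = "indentation_record")
}

#' Hertzian biphasic creep forward model
#'
#' Creep displacement of a rigid sphere (radius R) pressed into biphasic
#' cartilage under constant load P. The interstitial fluid initially carries
#' the load fraction `F0 = 1 - e_c/e_t` and depressurizes as
#' `F(t) = F0 exp(-t / tau(t))` with the poroelastic timescale
#' `tau = a(t)^2 / (e_t k)` set by the current contact radius
#' `a = sqrt(R d)`. The solid phase carries the rest, so at each time the
#' displacement solves the Hertz relation
#' \deqn{\frac{4}{3}\frac{E_c}{1-\nu^2}\sqrt{R}\, d^{3/2} = P\,(1 - F(t))}
#' by damped fixed-point iteration (relative tolerance 1e-9). The initial
#' response is governed by the tensile modulus (solid fraction `e_c/e_t`) and
#' the equilibrium by the compressive modulus: `d(Inf)` equals the Hertz
#' closed form `(3 P (1-nu^2) / (4 e_c sqrt(R)))^(2/3)`.
#'
#' @param params a [biphasic_params()].
#' @param load_N load magnitude, N.
#' @param radius_mm indenter radius, mm.
#' @param times sampling times, s, non-decreasing from 0.
#' @param tol relative fixed-point tolerance.
#' @param max_iter iteration cap.
#' @return numeric displacement series, mm (non-decreasing).
#' @export
hbc_forward <- function(params, load_N, radius_mm, times,
                        tol = 1e-9, max_iter = 500L) {
  stopifnot(inherits(params, "biphasic_params"))
  if (any(times < 0) || any(diff(times) < 0)) {
    stop_input("`times` must be non-decreasing from 0")
  }
  P <- abs(load_N)
  R <- radius_mm
  ec <- params$e_c_MPa
  et <- params$e_t_MPa
  k <- params$k_perm
  nu <- params$poisson
  d_eq <- (3 * P * (1 - nu^2) / (4 * ec * sqrt(R)))^(2 / 3)
  f0 <- 1 - ec / et

  d <- rep(d_eq * (1 - f0)^(2 / 3), length(times))  # exact t = 0 solution
  for (it in seq_len(max_iter)) {
    tau <- R * d / (et * k)          # a^2 = R d
    frac <- 1 - f0 * exp(-times / tau)
    d_new <- d_eq * frac^(2 / 3)
    delta <- max(abs(d_new - d) / d_eq)
    d <- 0.5 * d + 0.5 * d_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop_input("fixed-point solver did not converge (last step %.3g)", delta)
  }
  d
}

#' Invert a creep-indentation record for biphasic parameters
#'
#' Nonlinear least squares of [hbc_forward()] against the measured
#' displacement over `(e_c, e_t, k)`. Positivity and `e_t > e_c` are enforced
#' by the log parameterization `(log e_c, log(e_t - e_c), log k)`.
#' Levenberg-Marquardt runs from a declared multi-start grid (tensile/
#' compressive ratio x permeability decade) seeded by the Hertz equilibrium
#' estimate of `e_c` from the final displacement; among converged starts the
#' winner has the lowest SSE, ties broken by the lowest permeability. A fit
#' with r^2 below `r2_threshold` (default 0.95) is flagged `excluded`.
#'
#' @param record an [indentation_record()].
#' @param r2_threshold exclusion threshold on the coefficient of
#'   determination.
#' @param poisson solid-matrix Poisson ratio held fixed during the fit.
#' @param start_ratios,start_k multi-start grid: candidate `e_t/e_c` ratios
#'   and permeabilities (mm^4/(N s)).
#' @return Object of class `biphasic_fit`: list with `params`
#'   ([biphasic_params()] or NULL), `r2`, `rmse_mm`, `excluded`, `reason`.
#' @export
hbc_fit <- function(record, r2_threshold = 0.95, poisson = 0,
                    start_ratios = c(2, 8, 25), start_k = c(3e-4, 3e-3)) {
  stopifnot(inherits(record, "indentation_record"))
  times <- record$time_s
  y <- record$displacement_mm
  if (length(times) < 20L) {
    stop_input("at least 20 samples spanning the transient are required")
  }
  P <- record$load_N
  R <- record$radius_mm

  d_end <- max(y[length(y)], 1e-6)
  ec0 <- 3 * P * (1 - poisson^2) / (4 * sqrt(R) * d_end^(3 / 2))

  resid_fn <- function(theta) {
    ec <- exp(theta[1])
    et <- ec + exp(theta[2])
    k <- exp(theta[3])
    p <- structure(list(e_c_MPa = ec, e_t_MPa = et, k_perm = k,
                        poisson = poisson), class = "biphasic_params")
    hbc_forward(p, P, R, times) - y
  }

  sst <- sum((y - mean(y))^2)
  starts <- expand.grid(ratio = start_ratios, k = start_k)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- c(log(ec0), log(ec0 * (starts$ratio[i] - 1)), log(starts$k[i]))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    k_hat <- exp(fit$par[3])
    if (is.null(best) ||
        sse < best$sse * (1 - 1e-9) ||
        (sse <= best$sse * (1 + 1e-9) && k_hat < best$k)) {
      best <- list(par = fit$par, sse = sse, k = k_hat)
    }
    if (sst > 0 && best$sse / sst < 1e-12) break  # exact fit found
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, r2 = NA_real_, rmse_mm = NA_real_,
                          excluded = TRUE, reason = "non-convergence"),
                     class = "biphasic_fit"))
  }
  ec <- exp(best$par[1])
  et <- ec + exp(best$par[2])
  k <- exp(best$par[3])
  r2 <- if (sst > 0) 1 - best$sse / sst else if (best$sse == 0) 1 else -Inf
  excluded <- !is.finite(r2) || r2 < r2_threshold
  structure(
    list(params = biphasic_params(ec, et, k, poisson), r2 = r2,
         rmse_mm = sqrt(best$sse / length(y)), excluded = excluded,
         reason = if (excluded) "r2 below threshold" else NA_character_),
    class = "biphasic_fit"
  )
}

#' Aggregate point fits to facet-joint summaries with control normalization
#'
#' Averages the biphasic properties over the non-excluded indentation points
#' of each facet joint (up to 6: three superior, three inferior), then
#' normalizes each joint's means to the within-animal control joint
#' (default level "C3-C4"), whose normalized values are therefore exactly 1.
#'
#' @param fits data.frame with columns `animal`, `level`, `e_c_MPa`,
#'   `e_t_MPa`, `k_perm`, `excluded` (one row per indentation point).
#' @param control_level level label of the within-animal control joint.
#' @return data.frame with one row per animal x level: property means,
#'   `n_points_used`, and `*_norm` columns (NA with a warning when the
#'   animal's control joint is missing).
#' @export
aggregate_facet <- function(fits, control_level = "C3-C4") {
  need <- c("animal", "level", "e_c_MPa", "e_t_MPa", "k_perm", "excluded")
  if (!all(need %in% names(fits))) {
    stop_input("`fits` must have columns: %s", paste(need, collapse = ", "))
  }
  props <- c("e_c_MPa", "e_t_MPa", "k_perm")
  keys <- unique(fits[c("animal", "level")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- fits[fits$animal == keys$animal[i] & fits$level == keys$level[i], ]
    used <- sub[!sub$excluded, , drop = FALSE]
    means <- if (nrow(used)) colMeans(used[props]) else
      stats::setNames(rep(NA_real_, 3), props)
    data.frame(animal = keys$animal[i], level = keys$level[i],
               as.list(means), n_points_used = nrow(used),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (p in props) out[[paste0(p, "_norm")]] <- NA_real_
  for (a in unique(out$animal)) {
    ctrl <- out[out$animal == a & out$level == control_level, , drop = FALSE]
    if (nrow(ctrl) != 1L || any(is.na(ctrl[props]))) {
      warning(sprintf("animal %s: control level %s missing; normalization skipped",
                      a, control_level), call. = FALSE)
      next
    }
    sel <- out$animal == a
    for (p in props) {
      out[[paste0(p, "_norm")]][sel] <- out[[p]][sel] / ctrl[[p]]
    }
  }
  out
}
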