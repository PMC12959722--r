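# Load envelopes and detachment criteria for the fruit stem.
#
# The stem detaches the fruit when either the maximum axial (tensile) stress
# or the maximum bending stress exceeds the allowable stress; the two
# envelopes peak at different phase instants and are therefore evaluated
# separately. In the parallel / small-angle configurations a third mechanism
# exists: parametric instability, where the linearized oscillation grows
# without bound and no finite envelope applies.

#' Maximum axial force in the stem
#'
#' Perpendicular: `FT_max = m g + m a * thetadot_max^2` with
#' `thetadot_max = m a w^3 As / sqrt(D)`. Parallel:
#' `FT_max = m w^2 As + m a * (thetadot_max)^2` with
#' `thetadot_max = m a w^3 As theta0 / sqrt(D)` (the base-acceleration term
#' m a_A replaces the weight term). For a stem between the two
#' configurations the envelope is bracketed by the two cases and is
#' interpolated linearly in the orientation angle.
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()].
#' @param response Optional precomputed [stem_response()] for `sys`/`exc`.
#' @return Force in N, or NA if the response is unstable.
#' @export
axial_force_max <- function(sys, exc, response = NULL) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  if (is.null(response)) response <- stem_response(sys, exc)
  if (!isTRUE(response$stable)) return(NA_real_)
  p <- .resp_parts(sys, exc$omega, exc$amplitude)
  m <- sys$fruit_mass
  if (exc$orientation == "perpendicular") {
    tdot <- if (p$D > 0) m * sys$a * exc$omega^3 * exc$amplitude / sqrt(p$D) else 0
    m * sys$gravity + m * sys$a * tdot^2
  } else {
    tdot <- if (p$D > 0) {
      m * sys$a * exc$omega^3 * exc$amplitude * response$offset / sqrt(p$D)
    } else 0
    m * exc$omega^2 * exc$amplitude + m * sys$a * tdot^2
  }
}

#' Maximum bending moment in the stem
#'
#' Perpendicular:
#' `M_max = m a w^2 As * sqrt(K^2 + (mu w)^2) / sqrt((K - J w^2)^2 + (mu w)^2)`.
#' Parallel: the same expression multiplied by the constant offset theta0
#' (the gravitational moment is neglected, consistent with the small offset).
#' Small-angle stems are bracketed between the two cases.
#'
#' @inheritParams axial_force_max
#' @return Moment in N*m, or NA if the response is unstable.
#' @export
bending_moment_max <- function(sys, exc, response = NULL) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  if (is.null(response)) response <- stem_response(sys, exc)
  if (!isTRUE(response$stable)) return(NA_real_)
  p <- .resp_parts(sys, exc$omega, exc$amplitude)
  if (p$D == 0) return(0)
  base <- p$P * sqrt(sys$K^2 + (sys$mu * exc$omega)^2) / sqrt(p$D)
  if (exc$orientation == "perpendicular") base else base * response$offset
}

#' Detachment verdict for one fruit
#'
#' Runs the steady-state response and the stability classification, then
#' applies the separated stress criteria: axial stress `FT_max / S` and
#' bending stress `M_max / W` against the allowable stress. The mechanism is
#' `"instability"` whenever the parametric balance diverges,
#' `"stress_failure"` when either stress criterion is met, `"none"`
#' otherwise.
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()].
#' @return One-row tibble of class `load_envelope`: `omega_rad_s`, `zeta`,
#'   `orientation`, `FT_max_N`, `M_max_Nm`, `sigma_axial_Pa`,
#'   `sigma_bending_Pa`, `sigma_combined_Pa`, `detaches_by_tension`,
#'   `detaches_by_bending`, `mechanism`.
#' @export
detachment_verdict <- function(sys, exc) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  al <- allowable_loads(sys$stem_diameter, sys$stem_allowable_stress)
  response <- stem_response(sys, exc)
  if (!isTRUE(response$stable)) {
    out <- tibble(
      omega_rad_s = exc$omega, zeta = sys$zeta,
      orientation = exc$orientation,
      FT_max_N = NA_real_, M_max_Nm = NA_real_,
      sigma_axial_Pa = NA_real_, sigma_bending_Pa = NA_real_,
      sigma_combined_Pa = NA_real_,
      detaches_by_tension = NA, detaches_by_bending = NA,
      mechanism = "instability"
    )
    class(out) <- c("load_envelope", class(out))
    return(out)
  }
  ft <- axial_force_max(sys, exc, response)
  mm <- bending_moment_max(sys, exc, response)
  sig_a <- ft / al$area_m2
  sig_b <- mm / al$section_modulus_m3
  by_t <- sig_a >= sys$stem_allowable_stress
  by_b <- sig_b >= sys$stem_allowable_stress
  out <- tibble(
    omega_rad_s = exc$omega, zeta = sys$zeta, orientation = exc$orientation,
    FT_max_N = ft, M_max_Nm = mm,
    sigma_axial_Pa = sig_a, sigma_bending_Pa = sig_b,
    sigma_combined_Pa = sig_a + sig_b,
    detaches_by_tension = by_t, detaches_by_bending = by_b,
    mechanism = if (by_t || by_b) "stress_failure" else "none"
  )
  class(out) <- c("load_envelope", class(out))
  out
}

#' Minimum detachment frequency
#'
#' Smallest forcing frequency at which the verdict is not `"none"`, located
#' by a coarse ascending grid and deterministic bisection to 0.01 rad/s.
#'
#' @param sys A [stem_fruit_system()] (its damping is overridden by `zeta`).
#' @param amplitude Branch amplitude A_s, m (> 0).
#' @param orientation Orientation case.
#' @param zeta Damping ratio.
#' @param delta Inclination for `"small_angle"`, rad.
#' @param omega_max Search cap, rad/s; defaults to 3*omega0.
#' @return Frequency in rad/s, or NA if no detachment below `omega_max`.
#' @export
min_detachment_frequency <- function(sys, amplitude,
                                     orientation = c("perpendicular",
                                                     "parallel",
                                                     "small_angle"),
                                     zeta = 0, delta = 0, omega_max = NULL) {
  orientation <- match.arg(orientation)
  .check_positive(amplitude = amplitude)
  sys <- set_damping(sys, zeta)
  if (is.null(omega_max)) omega_max <- 3 * sys$omega0
  detaches <- function(w) {
    v <- detachment_verdict(sys, excitation(w, amplitude, orientation, delta))
    v$mechanism != "none"
  }
  grid <- seq(0.5, omega_max, by = 0.5)
  hit <- NA_real_
  for (w in grid) {
    if (detaches(w)) { hit <- w; break }
  }
  if (is.na(hit)) return(NA_real_)
  lo <- max(hit - 0.5, 1e-6)
  hi <- hit
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (detaches(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Load-envelope sweep
#'
#' Tabulates forces, moments, stresses and mechanisms over a frequency grid
#' and damping-ratio list for one orientation.
#'
#' @param sys A [stem_fruit_system()].
#' @param omega Frequency grid, rad/s.
#' @param zeta Damping ratios.
#' @param amplitude Branch amplitude A_s, m.
#' @param orientation Orientation case.
#' @param delta Inclination for `"small_angle"`, rad.
#' @return Tibble with one row per (omega, zeta), columns as in
#'   [detachment_verdict()].
#' @export
loads_sweep <- function(sys, omega, zeta, amplitude,
                        orientation = c("perpendicular", "parallel",
                                        "small_angle"),
                        delta = 0) {
  orientation <- match.arg(orientation)
  grid <- tidyr::expand_grid(omega = omega, zeta = zeta)
  out <- dplyr::bind_rows(purrr::pmap(grid, function(omega, zeta) {
    detachment_verdict(set_damping(sys, zeta),
                       excitation(omega, amplitude, orientation, delta))
  }))
  attr(out, "amplitude_m") <- amplitude
  out
}
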