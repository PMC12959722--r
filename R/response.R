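# Harmonic-balance steady states of the base-excited fruit-stem pendulum.
#
# The stem plus fruit is a torsional pendulum riding on the oscillating
# branch. Its steady state is approximated as a constant offset plus a
# fundamental-frequency sinusoid; higher harmonics generated by the
# parametric term are neglected. Three orientation cases of the stem
# relative to the excitation direction are covered:
#   perpendicular - direct forcing, no parametric term, zero offset;
#   parallel      - gravity sets a constant offset, the excitation enters
#                   parametrically and can destabilize the system;
#   small_angle   - parallel plus a small inclination delta, which feeds an
#                   additional direct forcing term but leaves the
#                   instability condition unchanged.

#' Construct an excitation
#'
#' @param omega Forcing angular frequency, rad/s (>= 0).
#' @param amplitude Branch oscillation amplitude A_s at the attachment
#'   point, m (>= 0).
#' @param orientation One of `"perpendicular"`, `"parallel"`,
#'   `"small_angle"`.
#' @param delta Inclination from the parallel configuration, rad; only used
#'   for `orientation = "small_angle"`. Values above ~0.26 rad stretch the
#'   small-angle expansion and trigger a warning.
#' @return Object of class `excitation`.
#' @export
excitation <- function(omega, amplitude,
                       orientation = c("perpendicular", "parallel",
                                       "small_angle"),
                       delta = 0) {
  orientation <- match.arg(orientation)
  if (omega < 0 || amplitude < 0) {
    rlang::abort("'omega' and 'amplitude' must be non-negative.")
  }
  if (orientation == "small_angle" && abs(delta) > pi / 12 + 1e-9) {
    rlang::warn("abs(delta) > 0.26 rad: outside the small-angle regime, results are extrapolated.")
  }
  structure(list(omega = omega, amplitude = amplitude,
                 orientation = orientation, delta = delta),
            class = "excitation")
}

.harmonic_response <- function(offset, theta_s, theta_c, phase, stable,
                               orientation) {
  structure(
    list(offset = offset, sine_amplitude = theta_s, cosine_amplitude = theta_c,
         fundamental_amplitude = sqrt(theta_s^2 + theta_c^2),
         phase = phase, stable = stable, orientation = orientation),
    class = "harmonic_response"
  )
}

# Shared pieces: D = (K - J w^2)^2 + (mu w)^2 and the parametric forcing
# magnitude P = m a w^2 As.
.resp_parts <- function(sys, omega, amplitude) {
  dk <- sys$K - sys$J * omega^2
  list(
    dk = dk,
    D = dk^2 + (sys$mu * omega)^2,
    P = sys$fruit_mass * sys$a * omega^2 * amplitude
  )
}

#' Steady state, stem perpendicular to the excitation
#'
#' Direct base excitation of the linearized pendulum (the gravity restoring
#' term is dropped in this case's derivation). The response is a pure
#' fundamental with amplitude
#' `m a w^2 As / sqrt((K - J w^2)^2 + (mu w)^2)` and phase lag
#' `atan2(mu w, K - J w^2)`; the two-argument arctangent keeps the phase in
#' (0, pi) across resonance so the amplitude stays positive and continuous.
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()] with orientation `"perpendicular"`.
#' @return A `harmonic_response`.
#' @export
perpendicular_response <- function(sys, exc) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  if (exc$orientation != "perpendicular") {
    rlang::abort("excitation orientation must be 'perpendicular'.")
  }
  p <- .resp_parts(sys, exc$omega, exc$amplitude)
  if (p$D == 0) {
    rlang::abort("Undamped resonance: omega equals omega0 with mu = 0; response is singular.")
  }
  amp <- p$P / sqrt(p$D)
  phase <- atan2(sys$mu * exc$omega, p$dk)
  # theta2 = amp * sin(w t - phase) = amp cos(phase) sin - amp sin(phase) cos
  .harmonic_response(offset = 0,
                     theta_s = amp * cos(phase),
                     theta_c = -amp * sin(phase),
                     phase = phase, stable = TRUE,
                     orientation = "perpendicular")
}

#' Steady state, stem parallel to the excitation
#'
#' Harmonic balance of the parametrically excited pendulum: gravity drives a
#' constant offset theta0 and the excitation multiplies the state. With
#' `D = (K - J w^2)^2 + (mu w)^2` and `P = m a w^2 As`,
#' `theta0 = 2 m g a D / (2 D K - P^2 (K - J w^2))`,
#' `theta_s = P (K - J w^2) theta0 / D`, `theta_c = -mu w P theta0 / D`.
#' When the offset denominator is non-positive the balance has no bounded
#' solution: the response is flagged unstable and the angles set to NA.
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()] with orientation `"parallel"`.
#' @return A `harmonic_response`; `stable = FALSE` marks parametric
#'   instability.
#' @export
parallel_response <- function(sys, exc) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  if (exc$orientation != "parallel") {
    rlang::abort("excitation orientation must be 'parallel'.")
  }
  .angle_offset_response(sys, exc$omega, exc$amplitude, delta = 0,
                         orientation = "parallel")
}

#' Steady state, stem at a small angle to the parallel configuration
#'
#' Same parametric balance as the parallel case with an extra direct forcing
#' proportional to the inclination delta:
#' `delta0 = (2 m g a D + P^2 (K - J w^2) delta) / (2 D K - P^2 (K - J w^2))`,
#' `delta_s = 2 P (K delta + m a g) (K - J w^2) / (2 D K - P^2 (K - J w^2))`,
#' `delta_c = -mu w delta_s / (K - J w^2)`.
#' The instability denominator is identical to the parallel case, so the
#' stability classification does not depend on delta. At `delta = 0` every
#' field reduces exactly to [parallel_response()].
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()] with orientation `"small_angle"`.
#' @param delta Optional override of `exc$delta`, rad.
#' @return A `harmonic_response`.
#' @export
small_angle_response <- function(sys, exc, delta = NULL) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  if (exc$orientation != "small_angle") {
    rlang::abort("excitation orientation must be 'small_angle'.")
  }
  if (is.null(delta)) delta <- exc$delta
  .angle_offset_response(sys, exc$omega, exc$amplitude, delta = delta,
                         orientation = "small_angle")
}

# Common harmonic-balance solution for the parallel (delta = 0) and
# small-angle cases.
.angle_offset_response <- function(sys, omega, amplitude, delta, orientation) {
  p <- .resp_parts(sys, omega, amplitude)
  mga <- sys$fruit_mass * sys$gravity * sys$a
  den <- 2 * p$D * sys$K - p$P^2 * p$dk
  if (den <= 0) {
    return(.harmonic_response(offset = NA_real_, theta_s = NA_real_,
                              theta_c = NA_real_, phase = NA_real_,
                              stable = FALSE, orientation = orientation))
  }
  offset <- (2 * mga * p$D + p$P^2 * p$dk * delta) / den
  theta_s <- 2 * p$P * (sys$K * delta + mga) * p$dk / den
  theta_c <- if (p$dk != 0) -sys$mu * omega / p$dk * theta_s else {
    # dk = 0: balance gives theta_s = 0 and theta_c = -P (offset+delta) / (mu w)
    -p$P * (offset + delta) / (sys$mu * omega)
  }
  phase <- atan2(sys$mu * omega, p$dk)
  .harmonic_response(offset = offset, theta_s = theta_s, theta_c = theta_c,
                     phase = phase, stable = TRUE, orientation = orientation)
}

#' Dispatch on excitation orientation
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()].
#' @return A `harmonic_response` from the case-specific solver.
#' @export
stem_response <- function(sys, exc) {
  switch(exc$orientation,
         perpendicular = perpendicular_response(sys, exc),
         parallel = parallel_response(sys, exc),
         small_angle = small_angle_response(sys, exc))
}

#' Frequency sweep of the stem steady state
#'
#' Vectorized steady-state table over a frequency grid and damping-ratio
#' list, the workhorse behind resonance plots.
#'
#' @param sys A [stem_fruit_system()] (its damping is overridden per row).
#' @param omega Frequency grid, rad/s.
#' @param zeta Damping ratios to sweep.
#' @param amplitude Branch amplitude A_s, m.
#' @param orientation Orientation case.
#' @param delta Inclination for `"small_angle"`, rad.
#' @return Tibble: `omega_rad_s`, `zeta`, `offset_rad`, `amplitude_rad`,
#'   `phase_rad`, `stable`.
#' @export
stem_sweep <- function(sys, omega, zeta, amplitude,
                       orientation = c("perpendicular", "parallel",
                                       "small_angle"),
                       delta = 0) {
  orientation <- match.arg(orientation)
  grid <- tidyr::expand_grid(omega = omega, zeta = zeta)
  out <- purrr::pmap(grid, function(omega, zeta) {
    r <- stem_response(set_damping(sys, zeta),
                       excitation(omega, amplitude, orientation, delta))
    tibble(omega_rad_s = omega, zeta = zeta, offset_rad = r$offset,
           amplitude_rad = r$fundamental_amplitude, phase_rad = r$phase,
           stable = r$stable)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "orientation") <- orientation
  attr(out, "amplitude_m") <- amplitude
  class(out) <- c("stem_sweep", class(out))
  out
}

#' @export
print.harmonic_response <- function(x, ...) {
  cat("<harmonic_response> [", x$orientation, "]\n", sep = "")
  if (isTRUE(x$stable)) {
    cat(sprintf("  offset    = %.5g rad\n", x$offset))
    cat(sprintf("  amplitude = %.5g rad (phase %.4g rad)\n",
                x$fundamental_amplitude, x$phase))
  } else {
    cat("  UNSTABLE: parametric balance has no bounded solution\n")
  }
  invisible(x)
}
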