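# Parametric instability of the parallel / small-angle stem configurations.
#
# The harmonic-balance offset diverges when
#   2 D K - P^2 (K - J w^2) <= 0,  D = (K - J w^2)^2 + (mu w)^2,
#   P = m a w^2 As,
# which is the first-harmonic instability criterion of the base-excited
# pendulum. At zero damping the band has closed-form edges: the lower edge
# solves chi-form frequency condition with chi = J / (m a As); the upper
# edge is the natural frequency omega0 (the K - J w^2 = 0 root excluded in
# the factorized zero-damping condition).

#' Instability denominator
#'
#' Returns `2 D K - P^2 (K - J w^2)`; the system is unstable exactly where
#' this aggregate is negative, and the instability boundary is its zero set.
#' Its units are a raw algebraic aggregate (N^2 m^2 * N m/rad); only the
#' sign carries meaning.
#'
#' @param sys A [stem_fruit_system()] (damping taken from the object).
#' @param omega Frequency, rad/s (vectorized).
#' @param amplitude Branch amplitude A_s, m.
#' @return Numeric vector, same length as `omega`.
#' @export
instability_denominator <- function(sys, omega, amplitude) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  dk <- sys$K - sys$J * omega^2
  D <- dk^2 + (sys$mu * omega)^2
  P <- sys$fruit_mass * sys$a * omega^2 * amplitude
  2 * D * sys$K - P^2 * dk
}

#' Zero-damping instability band
#'
#' With `chi = J / (m a As)` the lower edge is
#' `omega_lo = omega0 * sqrt(chi * (sqrt(chi^2 + 2) - chi))` and the upper
#' edge equals the natural frequency omega0. As the branch amplitude
#' vanishes (`chi -> Inf`) the band collapses onto omega0.
#'
#' @param sys A [stem_fruit_system()].
#' @param amplitude Branch amplitude A_s, m (> 0).
#' @return Named numeric vector `c(omega_lo, omega_hi)` in rad/s.
#' @export
zero_damping_band <- function(sys, amplitude) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  .check_positive(amplitude = amplitude)
  chi <- sys$J / (sys$fruit_mass * sys$a * amplitude)
  w0 <- sys$omega0
  # chi*(sqrt(chi^2+2)-chi) rewritten as 2*chi/(sqrt(chi^2+2)+chi) to avoid
  # cancellation at large chi (vanishing amplitude)
  c(omega_lo = w0 * sqrt(2 * chi / (sqrt(chi^2 + 2) + chi)), omega_hi = w0)
}

#' Damping ratio on the instability boundary
#'
#' Solves the boundary condition for zeta at a given frequency:
#' `zeta^2 = (P^2 (K - J w^2) - 2 K (K - J w^2)^2) / (8 J K^2 w^2)`.
#' Where the right-hand side is negative no boundary exists (the frequency
#' is stable at all damping levels) and NA is returned.
#'
#' @param sys A [stem_fruit_system()] (its damping is irrelevant here).
#' @param omega Frequency, rad/s (vectorized, > 0).
#' @param amplitude Branch amplitude A_s, m.
#' @return Numeric vector of boundary zeta values (NA where undefined).
#' @export
boundary_damping <- function(sys, omega, amplitude) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  if (any(omega <= 0)) rlang::abort("'omega' must be positive.")
  dk <- sys$K - sys$J * omega^2
  P <- sys$fruit_mass * sys$a * omega^2 * amplitude
  rhs <- (P^2 * dk - 2 * sys$K * dk^2) / (8 * sys$J * sys$K^2 * omega^2)
  # collar for roundoff at the exact band edge, where the two terms cancel
  scale <- (P^2 * abs(dk) + 2 * sys$K * dk^2) / (8 * sys$J * sys$K^2 * omega^2)
  rhs[rhs < 0 & rhs > -1e-12 * scale] <- 0
  out <- rep(NA_real_, length(rhs))
  out[rhs >= 0] <- sqrt(rhs[rhs >= 0])
  out
}

#' Critical damping ratio
#'
#' The largest damping ratio at which any frequency is unstable: the maximum
#' of [boundary_damping()] over frequency. Located deterministically by a
#' dense log-spaced scan over [1, 2*omega0] followed by golden-section
#' refinement.
#'
#' @param sys A [stem_fruit_system()].
#' @param amplitude Branch amplitude A_s, m.
#' @param n_scan Scan resolution.
#' @return List: `zeta_star`, `omega_star` (rad/s).
#' @export
critical_damping_ratio <- function(sys, amplitude, n_scan = 2000) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  grid <- exp(seq(log(1), log(2 * sys$omega0), length.out = n_scan))
  zb <- boundary_damping(sys, grid, amplitude)
  if (all(is.na(zb))) return(list(zeta_star = 0, omega_star = NA_real_))
  i <- which.max(zb)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_scan, i + 1)]
  opt <- stats::optimize(function(w) boundary_damping(sys, w, amplitude),
                         c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(zeta_star = opt$objective, omega_star = opt$maximum)
}

#' Instability predicate
#'
#' @param sys A [stem_fruit_system()] (its damping ratio is overridden).
#' @param omega Frequency, rad/s (vectorized).
#' @param zeta Damping ratio.
#' @param amplitude Branch amplitude A_s, m.
#' @return Logical vector: TRUE where the parametric balance diverges.
#' @export
is_unstable <- function(sys, omega, zeta, amplitude) {
  instability_denominator(set_damping(sys, zeta), omega, amplitude) < 0
}

#' Stability map over frequency and amplitude
#'
#' Tabulates the boundary damping ratio and zero-damping classification over
#' a frequency grid for one or more branch amplitudes, plus the band edges
#' and critical damping ratio per amplitude.
#'
#' @param sys A [stem_fruit_system()].
#' @param omega Frequency grid, rad/s.
#' @param amplitude One or more branch amplitudes, m.
#' @param zeta Damping ratio used for the `unstable` column.
#' @return Object of class `stability_map`: a tibble with columns
#'   `omega_rad_s`, `amplitude_m`, `zeta_boundary`, `unstable`; attributes
#'   `summary` (tibble of band edges and critical zeta per amplitude) and
#'   `zeta`.
#' @export
stability_map <- function(sys, omega, amplitude, zeta = 0) {
  rows <- purrr::map(amplitude, function(as_m) {
    tibble(
      omega_rad_s = omega,
      amplitude_m = as_m,
      zeta_boundary = boundary_damping(sys, omega, as_m),
      unstable = is_unstable(sys, omega, zeta, as_m)
    )
  })
  out <- dplyr::bind_rows(rows)
  summ <- dplyr::bind_rows(purrr::map(amplitude, function(as_m) {
    band <- zero_damping_band(sys, as_m)
    cz <- critical_damping_ratio(sys, as_m)
    tibble(amplitude_m = as_m, omega_lo_rad_s = band[["omega_lo"]],
           omega_hi_rad_s = band[["omega_hi"]], zeta_star = cz$zeta_star)
  }))
  attr(out, "summary") <- summ
  attr(out, "zeta") <- zeta
  class(out) <- c("stability_map", class(out))
  out
}
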