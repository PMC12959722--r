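# Uniform-strength branch: diameter profile and power-series steady state of
# the forced bending vibration. The coordinate z is measured from the branch
# tip (where the section vanishes); the series solution is clamped at the
# apical coordinate z_tip of the section system, and all series terms are
# powers of x = z - z_tip.

#' Diameter profile of a uniform-strength branch
#'
#' Under a distributed load q with equal maximum bending stress at every
#' section, the circular-section diameter follows
#' d(z) = (16 q / (pi sigma))^(1/3) z^(2/3) with z measured from the tip.
#'
#' @param z Coordinate from the branch tip, m (vectorized, `z >= 0`).
#' @param distributed_load q, N/m.
#' @param allowable_stress Design bending stress sigma, Pa.
#' @return Tibble with columns `z_m`, `diameter_m`, `area_m2`,
#'   `second_moment_m4`. The area satisfies A(z) = beta z^(4/3) and the
#'   second moment I(z) = A(z)^2/(4 pi) for the beta implied by q and sigma.
#' @export
diameter_profile <- function(z, distributed_load, allowable_stress) {
  .check_positive(distributed_load = distributed_load,
                  allowable_stress = allowable_stress)
  if (any(z < 0)) rlang::abort("'z' must be non-negative.")
  d <- (16 * distributed_load / (pi * allowable_stress))^(1 / 3) * z^(2 / 3)
  a <- pi * d^2 / 4
  tibble(z_m = z, diameter_m = d, area_m2 = a,
         second_moment_m4 = a^2 / (4 * pi))
}

#' Series coefficients of the branch steady-state deflection
#'
#' The steady-state bending deflection of the tapered branch under tip-normal
#' harmonic forcing `F sin(omega t)` is `f(z, t) = sin(omega t) * sum_k b_k
#' x^((8k+4)/3)` with x the distance from the clamped section. The leading
#' coefficient is b_0 = 9 pi F / (2 E beta^2) and the remaining terms follow
#' the recurrence
#' `b_{k+1} = b_k * G * 81 / ((8k+12)(8k+9)(8k+14)(8k+11))`,
#' `G = 4 pi rho omega^2 / (E beta)`,
#' obtained by substituting the series into the variable-section beam
#' equation term by term (the stiffness term of order k+1 balances the
#' inertia term of order k). The k = 1 coefficient reduces to
#' 27 pi^2 F rho omega^2 / (308 E^2 beta^3).
#'
#' @param force_amplitude F, N.
#' @param omega Forcing angular frequency, rad/s (`omega >= 0`).
#' @param elastic_modulus E, Pa.
#' @param beta Section proportionality coefficient, m^(2/3).
#' @param density rho, kg/m^3.
#' @param k_max Number of terms beyond b_0 to retain.
#' @return Object of class `branch_series`: list with `b` (coefficients
#'   b_0..b_{k_max}), `omega`, `force_amplitude`, `beta`, `elastic_modulus`,
#'   `density`, `k_max`.
#' @export
series_coefficients <- function(force_amplitude, omega, elastic_modulus, beta,
                                density, k_max = 8) {
  .check_positive(force_amplitude = force_amplitude,
                  elastic_modulus = elastic_modulus, beta = beta,
                  density = density)
  if (omega < 0) rlang::abort("'omega' must be non-negative.")
  if (k_max < 1) rlang::abort("'k_max' must be at least 1.")
  b <- numeric(k_max + 1)
  b[1] <- 9 * pi * force_amplitude / (2 * elastic_modulus * beta^2)
  g <- 4 * pi * density * omega^2 / (elastic_modulus * beta)
  for (k in 0:(k_max - 1)) {
    denom <- (8 * k + 12) * (8 * k + 9) * (8 * k + 14) * (8 * k + 11)
    b[k + 2] <- b[k + 1] * g * 81 / denom
  }
  structure(
    list(b = b, omega = omega, force_amplitude = force_amplitude,
         beta = beta, elastic_modulus = elastic_modulus, density = density,
         k_max = k_max),
    class = "branch_series"
  )
}

# Series terms b_k * x^((8k+4)/3) for scalar x >= 0.
.series_terms <- function(sol, x) {
  k <- seq_along(sol$b) - 1
  sol$b * x^((8 * k + 4) / 3)
}

#' Evaluate the branch deflection series
#'
#' @param z Coordinate from the branch tip, m (vectorized).
#' @param t Time, s (vectorized with `z`).
#' @param sol A [series_coefficients()] solution.
#' @param z_clamp Coordinate of the clamped section (the apical coordinate of
#'   the section system), m. Deflection is measured from this section.
#' @param tol Truncation check: the last retained term must contribute less
#'   than `tol` of the partial sum at the evaluation point furthest from the
#'   clamp; a last-term ratio at or above 1 is a convergence failure.
#' @return Deflection f(z, t) in m, same length as `z` recycled with `t`.
#' @export
branch_deflection <- function(z, t, sol, z_clamp, tol = 1e-10) {
  stopifnot(inherits(sol, "branch_series"))
  if (any(z < z_clamp)) rlang::abort("'z' must be at or beyond the clamped section.")
  n <- max(length(z), length(t))
  z <- rep_len(z, n); t <- rep_len(t, n)
  x_max <- max(z - z_clamp)
  if (x_max > 0) {
    terms <- .series_terms(sol, x_max)
    total <- sum(terms)
    last_ratio <- abs(terms[length(terms)]) / max(abs(total), .Machine$double.xmin)
    if (length(terms) >= 2 && abs(terms[length(terms)]) >= abs(terms[length(terms) - 1])) {
      rlang::abort(paste0(
        "Deflection series not converging at x = ", signif(x_max, 4),
        " m: last term ratio >= 1. Increase k_max or reduce omega/evaluation range."))
    }
    if (last_ratio > tol) {
      rlang::warn(paste0("Last retained series term contributes ",
                         signif(last_ratio, 3),
                         " of the sum; consider increasing k_max."))
    }
  }
  vapply(seq_len(n), function(i) {
    sum(.series_terms(sol, z[i] - z_clamp)) * sin(sol$omega * t[i])
  }, numeric(1))
}

#' First-term branch vibration amplitude
#'
#' Amplitude of the leading series term,
#' A_s(z) = 9 pi F / (2 E beta^2) * (z - z_clamp)^(4/3): the low-frequency
#' amplitude envelope of the branch, strictly increasing from the clamped
#' section to the free end.
#'
#' @inheritParams branch_deflection
#' @return Amplitude in m.
#' @export
branch_amplitude <- function(z, sol, z_clamp) {
  stopifnot(inherits(sol, "branch_series"))
  if (any(z < z_clamp)) rlang::abort("'z' must be at or beyond the clamped section.")
  sol$b[1] * (z - z_clamp)^(4 / 3)
}

#' Force amplitude reproducing a target tip amplitude
#'
#' Inverts the first-term amplitude at the branch root so that downstream
#' stem computations consume a prescribed machine amplitude (for example
#' 39 mm or 53 mm at the excitation point).
#'
#' @param target_amplitude Desired amplitude at `z = z_clamp + span`, m.
#' @param span Distance from the clamped section to the evaluation point, m.
#' @param elastic_modulus E, Pa.
#' @param beta Section coefficient, m^(2/3).
#' @return Force amplitude F, N.
#' @export
force_for_amplitude <- function(target_amplitude, span, elastic_modulus, beta) {
  .check_positive(target_amplitude = target_amplitude, span = span,
                  elastic_modulus = elastic_modulus, beta = beta)
  target_amplitude * 2 * elastic_modulus * beta^2 / (9 * pi * span^(4 / 3))
}

#' Branch amplitude sweep
#'
#' Tabulates the steady-state amplitude envelope along the branch for one
#' forcing condition; the shape feeding stem-level models.
#'
#' @param geom A [branch_geometry()].
#' @param omega Forcing frequency, rad/s.
#' @param force_amplitude F, N. Give either this or `tip_amplitude`.
#' @param tip_amplitude Target amplitude at the branch root end, m.
#' @param n_points Grid resolution along the branch.
#' @param k_max Series truncation.
#' @return Tibble: `z_m` (coordinate from tip), `x_m` (distance from clamp),
#'   `amplitude_m` (first-term envelope), `deflection_peak_m` (full truncated
#'   series at `sin(omega t) = 1`).
#' @export
branch_sweep <- function(geom, omega, force_amplitude = NULL,
                         tip_amplitude = NULL, n_points = 50, k_max = 8) {
  prof <- branch_section_coefficient(geom)
  if (is.null(force_amplitude) == is.null(tip_amplitude)) {
    rlang::abort("Give exactly one of 'force_amplitude' or 'tip_amplitude'.")
  }
  if (is.null(force_amplitude)) {
    force_amplitude <- force_for_amplitude(tip_amplitude, geom$length,
                                           geom$elastic_modulus, prof$beta)
  }
  sol <- series_coefficients(force_amplitude, omega, geom$elastic_modulus,
                             prof$beta, geom$density, k_max)
  z <- seq(prof$z_tip, prof$z_tip + geom$length, length.out = n_points)
  tibble(
    z_m = z,
    x_m = z - prof$z_tip,
    amplitude_m = branch_amplitude(z, sol, prof$z_tip),
    deflection_peak_m = branch_deflection(z, pi / (2 * max(omega, 1e-12)),
                                          sol, prof$z_tip)
  )
}
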