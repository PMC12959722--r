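# Independent numerical oracle for the analytic stem model: direct time
# integration of the full nonlinear governing equation and Floquet analysis
# of the linearized parametric equation. Everything here is deterministic
# given its inputs (fixed initial state, fixed tolerances), so oracle
# numbers can be frozen into tests.
#
# Governing equation (theta measured from the configuration's reference):
#   J theta'' + m a w^2 f cos(theta + theta20)
#     = m g a sin(theta + theta20) - K theta - mu theta',   f = As sin(w t).
# theta20 = pi is the perpendicular configuration, pi/2 the parallel one,
# pi/2 + delta the small-angle one. The analytic perpendicular solution
# drops the gravity restoring term during linearization; `gravity = "none"`
# integrates that same truncation so comparisons isolate the
# harmonic-balance error rather than the modelling difference.

.theta20 <- function(orientation, delta = 0) {
  switch(orientation,
         perpendicular = pi,
         parallel = pi / 2,
         small_angle = pi / 2 + delta,
         rlang::abort("unknown orientation"))
}

#' Integrate the nonlinear fruit-stem equation
#'
#' High-order adaptive integration (deSolve's `lsoda`) of the pendulum
#' equation as a first-order system, retaining the full trigonometric
#' nonlinearity. The default initial state is rest at the reference angle.
#'
#' @param sys A [stem_fruit_system()].
#' @param exc An [excitation()].
#' @param t_span Length of integration, s; default 60 forcing periods.
#' @param initial_state `c(theta, theta_dot)` at t = 0.
#' @param n_per_period Output samples per forcing period.
#' @param gravity `"full"` keeps the gravity torque of the governing
#'   equation; `"none"` removes it (matching the truncation under which the
#'   perpendicular closed form is derived).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `stem_trajectory`: tibble `time_s`, `theta_rad`,
#'   `theta_dot_rad_s`, with attributes `omega`, `diverged`.
#' @export
integrate_stem <- function(sys, exc, t_span = NULL,
                           initial_state = c(0, 0), n_per_period = 64,
                           gravity = c("full", "none"),
                           rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(sys, "stem_fruit_system"), inherits(exc, "excitation"))
  gravity <- match.arg(gravity)
  w <- exc$omega
  if (w <= 0) rlang::abort("'omega' must be positive for integration.")
  period <- 2 * pi / w
  if (is.null(t_span)) t_span <- 60 * period
  t20 <- .theta20(exc$orientation, exc$delta)
  g_eff <- if (gravity == "full") sys$gravity else 0
  m <- sys$fruit_mass; a <- sys$a; J <- sys$J; K <- sys$K; mu <- sys$mu
  As <- exc$amplitude
  rhs <- function(t, y, parms) {
    f <- As * sin(w * t)
    acc <- (m * g_eff * a * sin(y[1] + t20) - K * y[1] - mu * y[2] -
              m * a * w^2 * f * cos(y[1] + t20)) / J
    list(c(y[2], acc))
  }
  times <- seq(0, t_span, by = period / n_per_period)
  sol <- suppressWarnings(
    deSolve::lsoda(y = initial_state, times = times, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 50000)
  )
  sol <- as.data.frame(sol)
  diverged <- nrow(sol) < length(times) || any(!is.finite(sol[[2]])) ||
    max(abs(sol[[2]]), na.rm = TRUE) > 1e3
  out <- tibble(time_s = sol[[1]], theta_rad = sol[[2]],
                theta_dot_rad_s = sol[[3]])
  attr(out, "omega") <- w
  attr(out, "diverged") <- diverged
  class(out) <- c("stem_trajectory", class(out))
  out
}

#' Extract steady-state offset, amplitude and growth rate from a trajectory
#'
#' Least-squares fit of `theta(t) = c0 + cs sin(w t) + cc cos(w t)` over the
#' final `n_cycles` forcing periods, plus a growth-rate estimate from a
#' log-envelope regression of per-cycle amplitude over those periods. The
#' trajectory is deemed converged when the envelope growth rate is small
#' compared with the forcing frequency.
#'
#' @param traj A [integrate_stem()] trajectory.
#' @param omega Forcing frequency, rad/s; defaults to the trajectory's.
#' @param n_cycles Number of final periods used for the fit.
#' @return List of class `steady_state_estimate`: `offset`,
#'   `fundamental_amplitude`, `fundamental_phase`, `growth_rate` (1/s),
#'   `converged`.
#' @export
extract_steady_state <- function(traj, omega = NULL, n_cycles = 10) {
  stopifnot(inherits(traj, "stem_trajectory"))
  if (is.null(omega)) omega <- attr(traj, "omega")
  if (isTRUE(attr(traj, "diverged"))) {
    return(structure(list(offset = NA_real_, fundamental_amplitude = NA_real_,
                          fundamental_phase = NA_real_, growth_rate = Inf,
                          converged = FALSE),
                     class = "steady_state_estimate"))
  }
  period <- 2 * pi / omega
  t_end <- max(traj$time_s)
  tail <- traj[traj$time_s >= t_end - n_cycles * period, ]
  fit <- stats::lm(theta_rad ~ sin(omega * time_s) + cos(omega * time_s),
                   data = tail)
  cf <- stats::coef(fit)
  cs <- cf[[2]]; cc <- cf[[3]]
  # per-cycle deviation amplitude -> growth rate of the envelope
  cyc <- floor((tail$time_s - min(tail$time_s)) / period)
  counts <- table(cyc)
  complete <- names(counts)[counts >= 0.9 * stats::median(counts)]
  keep <- cyc %in% as.numeric(complete)
  env <- tapply(abs(tail$theta_rad[keep] - cf[[1]]), cyc[keep], max)
  env <- env[env > 0]
  growth <- if (length(env) >= 3) {
    tt <- (as.numeric(names(env)) + 0.5) * period
    stats::coef(stats::lm(log(env) ~ tt))[[2]]
  } else 0
  structure(
    list(offset = cf[[1]],
         fundamental_amplitude = sqrt(cs^2 + cc^2),
         fundamental_phase = atan2(-cc, cs),
         growth_rate = growth,
         converged = is.finite(growth) && abs(growth) < 0.02 * omega),
    class = "steady_state_estimate"
  )
}

#' Floquet classification of the parametric equation
#'
#' Linearizes the governing equation about the configuration's static
#' reference (the gravity droop angle solving `K theta = m g a cos(theta)`
#' for the parallel / small-angle cases, zero for the perpendicular case)
#' and integrates the two fundamental solutions over one forcing period to
#' form the monodromy matrix. The system is unstable when any Floquet
#' multiplier magnitude exceeds 1 + 1e-8 (a float-edge collar).
#'
#' @param sys A [stem_fruit_system()] (damping overridden by `zeta`).
#' @param omega Forcing frequency, rad/s.
#' @param zeta Damping ratio.
#' @param amplitude Branch amplitude A_s, m.
#' @param orientation Orientation case.
#' @param delta Inclination for `"small_angle"`, rad.
#' @return List: `unstable` (logical), `multipliers` (complex pair),
#'   `magnitudes`.
#' @export
floquet_classify <- function(sys, omega, zeta, amplitude,
                             orientation = c("parallel", "small_angle",
                                             "perpendicular"),
                             delta = 0) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  orientation <- match.arg(orientation)
  if (omega <= 0) rlang::abort("'omega' must be positive.")
  sys <- set_damping(sys, zeta)
  t20 <- .theta20(orientation, delta)
  m <- sys$fruit_mass; a <- sys$a; J <- sys$J; K <- sys$K; mu <- sys$mu
  g <- sys$gravity
  # static reference: K theta = m g a sin(theta + theta20) , f = 0
  ref <- stats::uniroot(function(th) K * th - m * g * a * sin(th + t20),
                        c(-1, 1), tol = 1e-12)$root
  # perturbation u about ref:
  # J u'' + mu u' + [K - m g a cos(ref + t20)
  #                  - m a w^2 As sin(w t) * (-sin(ref + t20))' ...] u = 0
  # linearized coefficient of u from the two trig terms:
  #   d/dtheta [ m a w^2 f cos(theta+t20) ] = -m a w^2 f sin(ref+t20)
  #   d/dtheta [ m g a sin(theta+t20) ]     =  m g a cos(ref+t20)
  stiff0 <- K - m * g * a * cos(ref + t20)
  par_coef <- -m * a * omega^2 * amplitude * sin(ref + t20)
  rhs <- function(t, y, parms) {
    kt <- stiff0 + par_coef * sin(omega * t)
    u1 <- y[1:2]; u2 <- y[3:4]
    list(c(u1[2], -(mu * u1[2] + kt * u1[1]) / J,
           u2[2], -(mu * u2[2] + kt * u2[1]) / J))
  }
  period <- 2 * pi / omega
  sol <- deSolve::lsoda(y = c(1, 0, 0, 1), times = c(0, period), func = rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-13,
                        maxsteps = 50000)
  yT <- as.numeric(sol[nrow(sol), -1])
  monodromy <- matrix(c(yT[1], yT[2], yT[3], yT[4]), nrow = 2)
  mult <- eigen(monodromy, only.values = TRUE)$values
  mags <- Mod(mult)
  list(unstable = any(mags > 1 + 1e-8), multipliers = mult, magnitudes = mags)
}

#' Analytic-vs-oracle comparison table
#'
#' For each (omega, zeta) pair, computes the harmonic-balance amplitude and
#' the ODE-extracted amplitude, their relative difference, and both
#' stability classifications (analytic sign test vs Floquet multipliers).
#'
#' @param sys A [stem_fruit_system()].
#' @param omega Frequencies, rad/s.
#' @param zeta Damping ratios.
#' @param amplitude Branch amplitude A_s, m.
#' @param orientation Orientation case.
#' @param delta Inclination, rad.
#' @param gravity Gravity mode passed to [integrate_stem()]; defaults to the
#'   truncation matching the orientation's closed form.
#' @return Tibble: `omega_rad_s`, `zeta`, `analytic_offset`,
#'   `analytic_amplitude`, `ode_offset`, `ode_amplitude`, `rel_diff`,
#'   `analytic_unstable`, `floquet_unstable`.
#' @export
oracle_compare <- function(sys, omega, zeta, amplitude,
                           orientation = c("perpendicular", "parallel",
                                           "small_angle"),
                           delta = 0, gravity = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(gravity)) {
    gravity <- if (orientation == "perpendicular") "none" else "full"
  }
  grid <- tidyr::expand_grid(omega = omega, zeta = zeta)
  dplyr::bind_rows(purrr::pmap(grid, function(omega, zeta) {
    s <- set_damping(sys, zeta)
    exc <- excitation(omega, amplitude, orientation, delta)
    resp <- stem_response(s, exc)
    an_unstable <- !isTRUE(resp$stable)
    fl <- floquet_classify(sys, omega, zeta, amplitude, orientation, delta)
    if (an_unstable || fl$unstable) {
      ode_off <- NA_real_; ode_amp <- NA_real_; rel <- NA_real_
    } else {
      traj <- integrate_stem(s, exc, gravity = gravity)
      ss <- extract_steady_state(traj)
      ode_off <- ss$offset; ode_amp <- ss$fundamental_amplitude
      rel <- abs(ode_amp - resp$fundamental_amplitude) /
        max(abs(resp$fundamental_amplitude), .Machine$double.eps)
    }
    tibble(omega_rad_s = omega, zeta = zeta,
           analytic_offset = resp$offset,
           analytic_amplitude = resp$fundamental_amplitude,
           ode_offset = ode_off, ode_amplitude = ode_amp, rel_diff = rel,
           analytic_unstable = an_unstable, floquet_unstable = fl$unstable)
  }))
}
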