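# Broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a harmonic response
#'
#' @param x A `harmonic_response`.
#' @param ... Unused.
#' @return One-row tibble of the steady-state quantities.
#' @method tidy harmonic_response
#' @export
tidy.harmonic_response <- function(x, ...) {
  tibble(orientation = x$orientation, offset_rad = x$offset,
         sine_amplitude_rad = x$sine_amplitude,
         cosine_amplitude_rad = x$cosine_amplitude,
         amplitude_rad = x$fundamental_amplitude,
         phase_rad = x$phase, stable = x$stable)
}

#' Tidy a steady-state estimate extracted from a trajectory
#'
#' @param x A `steady_state_estimate`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy steady_state_estimate
#' @export
tidy.steady_state_estimate <- function(x, ...) {
  tibble(offset_rad = x$offset, amplitude_rad = x$fundamental_amplitude,
         phase_rad = x$fundamental_phase, growth_rate_per_s = x$growth_rate,
         converged = x$converged)
}

#' Tidy / summarize a stability map
#'
#' `tidy()` returns the per-frequency boundary table; `glance()` the per
#' amplitude band edges and critical damping ratio.
#'
#' @param x A [stability_map()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stability_map
#' @export
tidy.stability_map <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stability_map")
  attr(out, "summary") <- NULL
  out
}

#' @rdname tidy.stability_map
#' @method glance stability_map
#' @export
glance.stability_map <- function(x, ...) attr(x, "summary")

#' Tidy / summarize a harvest outcome
#'
#' `tidy()` returns the per-fruit mechanism table, `glance()` the aggregate
#' masses and metrics.
#'
#' @param x A [run_harvest()] outcome.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy harvest_outcome
#' @export
tidy.harvest_outcome <- function(x, ...) x$per_fruit

#' @rdname tidy.harvest_outcome
#' @method glance harvest_outcome
#' @export
glance.harvest_outcome <- function(x, ...) x$summary

#' @export
print.harvest_outcome <- function(x, ...) {
  s <- x$summary
  cat("<harvest_outcome>\n")
  cat(sprintf("  omega = %.4g rad/s, As = %.4g m\n",
              s$omega_rad_s, s$amplitude_m))
  cat(sprintf("  k1 = %.2f%%, k2 = %.2f%% (m1 = %.4g kg, m2 = %.4g kg)\n",
              s$k1_pct, s$k2_pct, s$m1_kg, s$m2_kg))
  invisible(x)
}

#' Plot a stem frequency sweep
#'
#' Resonance curves of the steady-state angular amplitude against excitation
#' frequency, one line per damping ratio.
#'
#' @param object A [stem_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stem_sweep
#' @export
autoplot.stem_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$omega_rad_s, y = .data$amplitude_rad,
                               colour = factor(.data$zeta))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation frequency (rad/s)",
                  y = "angular amplitude (rad)",
                  colour = "damping ratio",
                  title = paste0("Stem steady-state amplitude (",
                                 attr(object, "orientation"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot a stability map
#'
#' Boundary damping ratio against excitation frequency; the region under
#' each curve is parametrically unstable.
#'
#' @param object A [stability_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_map
#' @export
autoplot.stability_map <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$zeta_boundary), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega_rad_s,
                                  y = .data$zeta_boundary,
                                  colour = factor(.data$amplitude_m))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "excitation frequency (rad/s)",
                  y = "boundary damping ratio",
                  colour = "branch amplitude (m)",
                  title = "Parametric instability boundary") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a harvest frequency sweep
#'
#' @param table A [harvest_table()] or [compare_orientation_cohorts()]
#'   tibble.
#' @return A ggplot object: harvest efficiency against frequency, faceted or
#'   coloured by amplitude/policy where present.
#' @export
plot_harvest_sweep <- function(table) {
  aes <- if ("policy" %in% names(table)) {
    ggplot2::aes(x = .data$omega_rad_s, y = .data$k1_pct,
                 colour = .data$policy)
  } else {
    ggplot2::aes(x = .data$omega_rad_s, y = .data$k1_pct,
                 colour = factor(.data$amplitude_m))
  }
  ggplot2::ggplot(table, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "excitation frequency (rad/s)",
                  y = "harvest efficiency k1 (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
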