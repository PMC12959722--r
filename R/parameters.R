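#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Standard gravity, m/s^2. SI default; no site-specific value is assumed.
.G_DEFAULT <- 9.81

#' Unit registry for parameter files
#'
#' Multiplicative factors converting a declared unit string to base SI.
#' Frequencies are handled separately (see [to_rad_s()]) because r/min to
#' rad/s is the only non-metric conversion the package needs.
#' @noRd
.unit_factor <- function(unit) {
  factors <- c(
    "m" = 1, "mm" = 1e-3, "cm" = 1e-2,
    "kg" = 1, "g" = 1e-3,
    "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6, "GPa" = 1e9,
    "kg/m^3" = 1, "N/m" = 1, "N" = 1, "N*m" = 1,
    "rad" = 1, "dimensionless" = 1
  )
  if (!unit %in% names(factors)) {
    abort(paste0("Unknown unit '", unit, "' in parameter file."))
  }
  factors[[unit]]
}

#' Convert a frequency value to rad/s
#'
#' Accepts explicit unit strings `"rad/s"` or `"rpm"` (revolutions per
#' minute, converted with 2*pi/60). A missing or unrecognized unit is an
#' error: frequency inputs must always declare their unit because field
#' practice mixes motor speeds (r/min) with angular frequencies (rad/s).
#'
#' @param x Numeric vector of frequencies.
#' @param unit One of `"rad/s"`, `"rpm"`.
#' @return Numeric vector in rad/s.
#' @examples
#' to_rad_s(300, "rpm") # 31.42 rad/s
#' @export
to_rad_s <- function(x, unit) {
  if (missing(unit) || length(unit) != 1 || !unit %in% c("rad/s", "rpm")) {
    abort("Frequency unit must be given explicitly: 'rad/s' or 'rpm'.")
  }
  if (unit == "rpm") x * 2 * pi / 60 else x
}

.check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("'", nm, "' must be a positive finite number."))
    }
  }
  invisible(TRUE)
}

#' Branch geometry
#'
#' Material and end-geometry constants of a fruit-bearing branch modelled as
#' a uniform-strength cantilever: equal maximum bending stress at every
#' cross-section under a distributed load, which forces the diameter law
#' d(z) proportional to z^(2/3) measured from the tip.
#'
#' @param length Branch length L, m.
#' @param basal_diameter Diameter at the thick (root) end, m.
#' @param apical_diameter Diameter at the thin (tip) end, m. Must be smaller
#'   than `basal_diameter`.
#' @param density Wood density, kg/m^3.
#' @param elastic_modulus Elastic modulus E, Pa.
#' @param allowable_stress Allowable bending stress, Pa.
#' @param distributed_load Optional distributed load q, N/m; only consumed by
#'   the closed-form diameter profile.
#' @return An object of class `branch_geometry` (a named list).
#' @examples
#' bg <- branch_geometry(0.885, 9.3e-3, 2.9e-3, 887, 5023e6, 35.3e6)
#' @export
branch_geometry <- function(length, basal_diameter, apical_diameter,
                            density, elastic_modulus, allowable_stress,
                            distributed_load = NULL) {
  .check_positive(
    length = length, basal_diameter = basal_diameter,
    apical_diameter = apical_diameter, density = density,
    elastic_modulus = elastic_modulus, allowable_stress = allowable_stress
  )
  if (!is.null(distributed_load)) .check_positive(distributed_load = distributed_load)
  if (basal_diameter <= apical_diameter) {
    abort("basal_diameter must exceed apical_diameter (the branch tapers tipward).")
  }
  structure(
    list(
      length = length, basal_diameter = basal_diameter,
      apical_diameter = apical_diameter, density = density,
      elastic_modulus = elastic_modulus, allowable_stress = allowable_stress,
      distributed_load = distributed_load
    ),
    class = "branch_geometry"
  )
}

#' Section proportionality coefficient of the tapered branch
#'
#' Solves the three-equation system A_tip = beta*z_tip^(4/3),
#' A_root = beta*z_root^(4/3), z_root - z_tip = L for the proportionality
#' coefficient beta and the tip/root coordinates, where the end areas are the
#' circular areas of the measured end diameters. Elimination gives the closed
#' form z_root/z_tip = (A_root/A_tip)^(3/4), so no iteration is needed.
#'
#' @param geom A [branch_geometry()].
#' @return A list of class `branch_profile` with elements `beta` (m^(2/3)),
#'   `z_tip`, `z_root` (m), and the end areas `area_tip`, `area_root` (m^2).
#' @examples
#' bg <- branch_geometry(0.885, 9.3e-3, 2.9e-3, 887, 5023e6, 35.3e6)
#' branch_section_coefficient(bg)$beta # ~6.2e-5 m^(2/3)
#' @export
branch_section_coefficient <- function(geom) {
  stopifnot(inherits(geom, "branch_geometry"))
  a_tip <- pi * (geom$apical_diameter / 2)^2
  a_root <- pi * (geom$basal_diameter / 2)^2
  ratio <- (a_root / a_tip)^(3 / 4) # z_root / z_tip
  if (!is.finite(ratio) || ratio <= 1) {
    abort("Degenerate geometry: end diameters equal, coordinate system has no solution.")
  }
  z_tip <- geom$length / (ratio - 1)
  z_root <- z_tip * ratio
  beta <- a_tip / z_tip^(4 / 3)
  structure(
    list(beta = beta, z_tip = z_tip, z_root = z_root,
         area_tip = a_tip, area_root = a_root),
    class = "branch_profile"
  )
}

#' Torsional stiffness of the fruit stem
#'
#' The stem is a short cantilever of circular cross-section; its resistance
#' to rotation of the rigid fruit is approximated by K = E*I_b/l with
#' I_b = pi*d^4/64.
#'
#' @param stem_length Stem length l, m.
#' @param stem_diameter Stem diameter d, m.
#' @param modulus Elastic modulus E, Pa.
#' @return Stiffness K in N*m/rad.
#' @examples
#' stem_stiffness(7.3e-3, 0.53e-3, 5023e6)
#' @export
stem_stiffness <- function(stem_length, stem_diameter, modulus) {
  .check_positive(stem_length = stem_length, stem_diameter = stem_diameter,
                  modulus = modulus)
  modulus * (pi * stem_diameter^4 / 64) / stem_length
}

#' Fruit inertia about the stem root
#'
#' The fruit is modelled as a uniform ellipsoid with semi-axes Lf/2 (long)
#' and Wf/2 (both transverse axes). Swinging about the stem-branch junction,
#' the centre of mass sits at a = l + Lf/2 and the transverse moment of
#' inertia about the centre of mass is I = (m/5)*((Wf/2)^2 + (Lf/2)^2);
#' the parallel-axis theorem gives the pendulum inertia J = I + m*a^2.
#' The ellipsoid idealisation and lever arm are a reconstruction: no
#' explicit fruit inertia is reported for this crop, and this is the simple
#' choice consistent with the system's measured natural frequency.
#'
#' @param fruit_mass m, kg.
#' @param fruit_length Long-axis length Lf, m.
#' @param fruit_width Transverse width Wf, m.
#' @param stem_length Stem length l, m.
#' @return A list with `a` (m), `inertia_com` (kg*m^2) and `inertia_total`
#'   (kg*m^2).
#' @examples
#' fruit_inertia(0.86e-3, 18.21e-3, 7.68e-3, 7.3e-3)
#' @export
fruit_inertia <- function(fruit_mass, fruit_length, fruit_width, stem_length) {
  .check_positive(fruit_mass = fruit_mass, fruit_length = fruit_length,
                  fruit_width = fruit_width, stem_length = stem_length)
  a <- stem_length + fruit_length / 2
  i_com <- fruit_mass / 5 * ((fruit_width / 2)^2 + (fruit_length / 2)^2)
  list(a = a, inertia_com = i_com, inertia_total = i_com + fruit_mass * a^2)
}

#' Fruit-stem pendulum system
#'
#' Assembles the torsional-pendulum constants of a single fruit hanging from
#' its stem: stiffness K from the stem's bending compliance, inertia
#' J = I + m*a^2 from the ellipsoidal fruit, and viscous damping given either
#' as a damping ratio `zeta` (the default parameterisation) or a raw
#' coefficient `mu`; the other is derived through zeta = mu/(2*sqrt(K*J)).
#'
#' @param stem_length l, m.
#' @param stem_diameter d, m.
#' @param stem_modulus E, Pa.
#' @param stem_allowable_stress Allowable stress of the stem, Pa.
#' @param fruit_mass m, kg.
#' @param fruit_length Lf, m.
#' @param fruit_width Wf, m.
#' @param zeta Damping ratio (dimensionless). Exactly one of `zeta`, `mu`.
#' @param mu Damping coefficient, N*m*s/rad.
#' @param gravity g, m/s^2.
#' @return An object of class `stem_fruit_system`: a named list carrying the
#'   inputs plus derived `K`, `a`, `inertia_com`, `J`, `mu`, `zeta`, `omega0`.
#' @examples
#' sys <- stem_fruit_system(7.3e-3, 0.53e-3, 5023e6, 35.3e6,
#'                          0.86e-3, 18.21e-3, 7.68e-3, zeta = 0.1)
#' sys$omega0 # ~103.6 rad/s
#' @export
stem_fruit_system <- function(stem_length, stem_diameter, stem_modulus,
                              stem_allowable_stress, fruit_mass, fruit_length,
                              fruit_width, zeta = NULL, mu = NULL,
                              gravity = .G_DEFAULT) {
  .check_positive(stem_allowable_stress = stem_allowable_stress,
                  gravity = gravity)
  K <- stem_stiffness(stem_length, stem_diameter, stem_modulus)
  fi <- fruit_inertia(fruit_mass, fruit_length, fruit_width, stem_length)
  J <- fi$inertia_total
  if (is.null(zeta) && is.null(mu)) zeta <- 0
  if (!is.null(zeta) && !is.null(mu)) {
    abort("Give either 'zeta' or 'mu', not both.")
  }
  if (is.null(mu)) {
    if (zeta < 0) abort("'zeta' must be non-negative.")
    mu <- 2 * zeta * sqrt(K * J)
  } else {
    if (mu < 0) abort("'mu' must be non-negative.")
    zeta <- mu / (2 * sqrt(K * J))
  }
  structure(
    list(
      stem_length = stem_length, stem_diameter = stem_diameter,
      stem_modulus = stem_modulus,
      stem_allowable_stress = stem_allowable_stress,
      fruit_mass = fruit_mass, fruit_length = fruit_length,
      fruit_width = fruit_width, gravity = gravity,
      K = K, a = fi$a, inertia_com = fi$inertia_com, J = J,
      mu = mu, zeta = zeta, omega0 = sqrt(K / J)
    ),
    class = "stem_fruit_system"
  )
}

#' Replace the damping of a system
#'
#' Returns a copy of a [stem_fruit_system()] with the damping ratio changed
#' and the coefficient mu re-derived; all other fields untouched. Convenient
#' in sweeps over zeta.
#'
#' @param sys A `stem_fruit_system`.
#' @param zeta New damping ratio.
#' @return A `stem_fruit_system`.
#' @export
set_damping <- function(sys, zeta) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  if (zeta < 0) abort("'zeta' must be non-negative.")
  sys$zeta <- zeta
  sys$mu <- 2 * zeta * sqrt(sys$K * sys$J)
  sys
}

#' Natural angular frequency of the fruit-stem pendulum
#'
#' @param sys A [stem_fruit_system()].
#' @return omega0 = sqrt(K/J), rad/s.
#' @export
natural_frequency <- function(sys) {
  stopifnot(inherits(sys, "stem_fruit_system"))
  sqrt(sys$K / sys$J)
}

#' Allowable section loads of the fruit stem
#'
#' Cross-section area S = pi*d^2/4, section modulus W = pi*d^3/32, and the
#' corresponding allowable axial force sigma*S and bending moment sigma*W at
#' the stem's allowable stress. Exceeding either load detaches the fruit.
#'
#' @param stem_diameter d, m.
#' @param allowable_stress Allowable stress of the stem, Pa.
#' @return A one-row tibble: `area_m2`, `section_modulus_m3`,
#'   `allowable_force_N`, `allowable_moment_Nm`.
#' @examples
#' allowable_loads(0.53e-3, 35.3e6) # ~7.79 N, ~0.00052 N*m
#' @export
allowable_loads <- function(stem_diameter, allowable_stress) {
  .check_positive(stem_diameter = stem_diameter,
                  allowable_stress = allowable_stress)
  s <- pi * stem_diameter^2 / 4
  w <- pi * stem_diameter^3 / 32
  tibble(
    area_m2 = s,
    section_modulus_m3 = w,
    allowable_force_N = allowable_stress * s,
    allowable_moment_Nm = allowable_stress * w
  )
}

# ---- parameter file I/O -----------------------------------------------------

#' Read a parameter file
#'
#' Parameter files are flat YAML: one entry per measured quantity, each with
#' fields `mean`, `sd` and an explicit `unit` string. Values are converted to
#' SI on read. The packaged fixture `blue_honeysuckle.yaml` carries the
#' field-measured means and standard deviations for Blue Honeysuckle.
#'
#' @param path Path to a YAML parameter file.
#' @return A tibble with columns `parameter`, `mean`, `sd` (SI units) and
#'   `unit` (the declared, pre-conversion unit).
#' @seealso [honeysuckle_params()] for the packaged fixture,
#'   [write_params()] for the inverse.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(entry, name) {
    if (!all(c("mean", "sd", "unit") %in% names(entry))) {
      abort(paste0("Parameter '", name, "' must have fields mean, sd, unit."))
    }
    f <- .unit_factor(entry$unit)
    tibble(parameter = name, mean = entry$mean * f, sd = entry$sd * f,
           unit = entry$unit)
  })
  dplyr::bind_rows(rows)
}

#' Write a parameter table back to YAML
#'
#' Inverse of [read_params()]: converts SI values back into each row's
#' declared unit and writes the flat YAML layout. A write/read round trip
#' reproduces every value to floating-point precision.
#'
#' @param params Tibble as returned by [read_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  entries <- purrr::pmap(params, function(parameter, mean, sd, unit) {
    f <- .unit_factor(unit)
    list(mean = mean / f, sd = sd / f, unit = unit)
  })
  names(entries) <- params$parameter
  yaml::write_yaml(entries, path, precision = 15)
  invisible(path)
}

#' Packaged Blue Honeysuckle parameter set
#'
#' Loads the packaged field-measurement fixture (means and standard
#' deviations of branch, stem and fruit properties for Blue Honeysuckle).
#'
#' @return A tibble as from [read_params()].
#' @export
honeysuckle_params <- function() {
  read_params(system.file("extdata", "blue_honeysuckle.yaml",
                          package = "stemshake", mustWork = TRUE))
}

.param_mean <- function(params, name) {
  v <- params$mean[params$parameter == name]
  if (length(v) != 1) abort(paste0("Parameter '", name, "' not found."))
  v
}

#' Build model objects from a parameter table
#'
#' Convenience constructors turning a parameter table (means) into the two
#' model objects. The stem shares the measured elastic modulus and allowable
#' stress with the branch, as in the source measurements.
#'
#' @param params Tibble from [read_params()]; defaults to the packaged
#'   Blue Honeysuckle fixture.
#' @param zeta Damping ratio for the stem system (not a measured quantity).
#' @return `default_branch()`: a [branch_geometry()]; `default_system()`:
#'   a [stem_fruit_system()].
#' @export
default_branch <- function(params = honeysuckle_params()) {
  branch_geometry(
    length = .param_mean(params, "branch_length"),
    basal_diameter = .param_mean(params, "branch_basal_diameter"),
    apical_diameter = .param_mean(params, "branch_apical_diameter"),
    density = .param_mean(params, "branch_density"),
    elastic_modulus = .param_mean(params, "branch_modulus"),
    allowable_stress = .param_mean(params, "allowable_stress")
  )
}

#' @rdname default_branch
#' @export
default_system <- function(params = honeysuckle_params(), zeta = 0) {
  stem_fruit_system(
    stem_length = .param_mean(params, "stem_length"),
    stem_diameter = .param_mean(params, "stem_diameter"),
    stem_modulus = .param_mean(params, "branch_modulus"),
    stem_allowable_stress = .param_mean(params, "allowable_stress"),
    fruit_mass = .param_mean(params, "fruit_mass"),
    fruit_length = .param_mean(params, "fruit_length"),
    fruit_width = .param_mean(params, "fruit_width"),
    zeta = zeta
  )
}

#' Summary of all derived scalars
#'
#' One flat named list of every secondary constant the model derives from a
#' parameter set, suitable for JSON export and run logging.
#'
#' @param params Parameter tibble; defaults to the packaged fixture.
#' @return Named list: beta, K, J, a, I, omega0, S, W, allowable_force,
#'   allowable_moment.
#' @export
derived_constants <- function(params = honeysuckle_params()) {
  geom <- default_branch(params)
  sys <- default_system(params)
  prof <- branch_section_coefficient(geom)
  al <- allowable_loads(sys$stem_diameter, sys$stem_allowable_stress)
  list(
    beta = prof$beta, K = sys$K, J = sys$J, a = sys$a, I = sys$inertia_com,
    omega0 = sys$omega0, S = al$area_m2, W = al$section_modulus_m3,
    allowable_force = al$allowable_force_N,
    allowable_moment = al$allowable_moment_Nm
  )
}

#' @export
print.stem_fruit_system <- function(x, ...) {
  cat("<stem_fruit_system>\n")
  cat(sprintf("  K      = %.4g N*m/rad\n", x$K))
  cat(sprintf("  J      = %.4g kg*m^2\n", x$J))
  cat(sprintf("  a      = %.4g m\n", x$a))
  cat(sprintf("  zeta   = %.4g\n", x$zeta))
  cat(sprintf("  omega0 = %.4g rad/s\n", x$omega0))
  invisible(x)
}

#' @export
print.branch_geometry <- function(x, ...) {
  cat("<branch_geometry>\n")
  cat(sprintf("  L = %.4g m, d_basal = %.4g m, d_apical = %.4g m\n",
              x$length, x$basal_diameter, x$apical_diameter))
  cat(sprintf("  rho = %.4g kg/m^3, E = %.4g Pa\n", x$density, x$elastic_modulus))
  invisible(x)
}
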