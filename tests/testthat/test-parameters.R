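test_that("section coefficient solves the three-equation system (independent root-finding route)", {
  prof <- branch_section_coefficient(hs_branch)
  a_tip <- pi * (hs_branch$apical_diameter / 2)^2
  a_root <- pi * (hs_branch$basal_diameter / 2)^2

  # independent oracle: eliminate beta, solve for z_tip by bisection on
  # A_root/A_tip = ((z_tip + L)/z_tip)^(4/3)
  f <- function(z1) ((z1 + hs_branch$length) / z1)^(4 / 3) - a_root / a_tip
  z1_star <- uniroot(f, c(1e-4, 10), tol = 1e-14)$root
  beta_star <- a_tip / z1_star^(4 / 3)

  expect_equal(prof$beta, beta_star, tolerance = 1e-10)
  expect_equal(prof$z_root - prof$z_tip, hs_branch$length, tolerance = 1e-12)
  expect_equal(prof$beta * prof$z_tip^(4 / 3), a_tip, tolerance = 1e-9)
  expect_equal(prof$beta * prof$z_root^(4 / 3), a_root, tolerance = 1e-9)
})

test_that("section coefficient scales linearly with end areas and rejects degenerate geometry", {
  prof <- branch_section_coefficient(hs_branch)
  # scaling both end areas by s means scaling both diameters by sqrt(s)
  s <- 2
  scaled <- branch_geometry(hs_branch$length,
                            hs_branch$basal_diameter * sqrt(s),
                            hs_branch$apical_diameter * sqrt(s),
                            hs_branch$density, hs_branch$elastic_modulus,
                            hs_branch$allowable_stress)
  prof_s <- branch_section_coefficient(scaled)
  expect_equal(prof_s$beta, s * prof$beta, tolerance = 1e-12)
  expect_equal(prof_s$z_tip, prof$z_tip, tolerance = 1e-12)
  expect_equal(prof_s$z_root, prof$z_root, tolerance = 1e-12)

  expect_error(
    branch_geometry(0.885, 5e-3, 5e-3, 887, 5023e6, 35.3e6),
    "taper"
  )
  expect_error(
    branch_geometry(-1, 9.3e-3, 2.9e-3, 887, 5023e6, 35.3e6),
    "positive"
  )
})

test_that("stem stiffness follows the d^4 and 1/l laws", {
  K <- stem_stiffness(7.3e-3, 0.53e-3, 5023e6)
  expect_equal(K, 5023e6 * pi * (0.53e-3)^4 / 64 / 7.3e-3, tolerance = 1e-14)
  expect_equal(stem_stiffness(7.3e-3, 2 * 0.53e-3, 5023e6), 16 * K,
               tolerance = 1e-12)
  expect_equal(stem_stiffness(2 * 7.3e-3, 0.53e-3, 5023e6), K / 2,
               tolerance = 1e-12)
  expect_error(stem_stiffness(0, 0.53e-3, 5023e6), "positive")
})

test_that("fruit inertia: ellipsoid formula, sphere limit, linearity in mass", {
  fi <- fruit_inertia(0.86e-3, 18.21e-3, 7.68e-3, 7.3e-3)
  expect_equal(fi$a, 7.3e-3 + 18.21e-3 / 2, tolerance = 1e-14)
  expect_equal(fi$inertia_total, fi$inertia_com + 0.86e-3 * fi$a^2,
               tolerance = 1e-14)

  # sphere limit: equal axes give the uniform-sphere transverse inertia
  sph <- fruit_inertia(1e-3, 10e-3, 10e-3, 5e-3)
  expect_equal(sph$inertia_com, 1e-3 / 5 * ((10e-3)^2 / 2), tolerance = 1e-12)

  # doubling the mass doubles both inertias, leaves the arm unchanged
  fi2 <- fruit_inertia(2 * 0.86e-3, 18.21e-3, 7.68e-3, 7.3e-3)
  expect_equal(fi2$a, fi$a)
  expect_equal(fi2$inertia_com, 2 * fi$inertia_com, tolerance = 1e-12)
  expect_equal(fi2$inertia_total, 2 * fi$inertia_total, tolerance = 1e-12)
})

test_that("natural frequency of the mean system reproduces the measured value and scales as sqrt(K/J)", {
  sys <- hs_sys()
  w0 <- natural_frequency(sys)
  expect_gt(w0, 103.0)
  expect_lt(w0, 104.2)

  sys4 <- sys
  sys4$K <- 4 * sys$K
  expect_equal(natural_frequency(sys4), 2 * w0, tolerance = 1e-12)
  sysJ <- sys
  sysJ$J <- 4 * sys$J
  expect_equal(natural_frequency(sysJ), w0 / 2, tolerance = 1e-12)
})

test_that("damping parameterisations round-trip through zeta = mu/(2 sqrt(KJ))", {
  s1 <- hs_sys(zeta = 0.17)
  s2 <- stem_fruit_system(s1$stem_length, s1$stem_diameter, s1$stem_modulus,
                          s1$stem_allowable_stress, s1$fruit_mass,
                          s1$fruit_length, s1$fruit_width, mu = s1$mu)
  expect_equal(s2$zeta, 0.17, tolerance = 1e-12)
  expect_equal(set_damping(s2, 0.3)$mu, 2 * 0.3 * sqrt(s1$K * s1$J),
               tolerance = 1e-12)
  expect_error(
    stem_fruit_system(s1$stem_length, s1$stem_diameter, s1$stem_modulus,
                      s1$stem_allowable_stress, s1$fruit_mass,
                      s1$fruit_length, s1$fruit_width, zeta = 0.1, mu = 1e-5),
    "either"
  )
})

test_that("allowable loads follow the d^2 and d^3 section laws", {
  al <- allowable_loads(0.53e-3, 35.3e6)
  expect_equal(al$area_m2, pi * (0.53e-3)^2 / 4, tolerance = 1e-14)
  expect_equal(al$section_modulus_m3, pi * (0.53e-3)^3 / 32, tolerance = 1e-14)
  al2 <- allowable_loads(2 * 0.53e-3, 35.3e6)
  expect_equal(al2$allowable_force_N, 4 * al$allowable_force_N,
               tolerance = 1e-12)
  expect_equal(al2$allowable_moment_Nm, 8 * al$allowable_moment_Nm,
               tolerance = 1e-12)
})

test_that("parameter files round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_params(hs_params, tmp)
  back <- read_params(tmp)
  expect_equal(back$parameter, hs_params$parameter)
  expect_equal(back$mean, hs_params$mean, tolerance = 1e-12)
  expect_equal(back$sd, hs_params$sd, tolerance = 1e-12)
  expect_equal(back$unit, hs_params$unit)
})

test_that("frequency conversion demands an explicit unit", {
  expect_equal(to_rad_s(300, "rpm"), 31.41593, tolerance = 1e-6)
  expect_equal(to_rad_s(700, "rpm"), 73.30383, tolerance = 1e-6)
  expect_equal(to_rad_s(31.42, "rad/s"), 31.42)
  expect_error(to_rad_s(300), "unit")
  expect_error(to_rad_s(300, "Hz"), "unit")
})

test_that("derived constants summary is complete and internally consistent", {
  con <- derived_constants(hs_params)
  expect_named(con, c("beta", "K", "J", "a", "I", "omega0", "S", "W",
                      "allowable_force", "allowable_moment"))
  expect_equal(con$omega0, sqrt(con$K / con$J), tolerance = 1e-12)
  sys <- hs_sys()
  expect_equal(con$J, con$I + sys$fruit_mass * con$a^2, tolerance = 1e-12)
  expect_equal(con$allowable_force, 35.3e6 * con$S, tolerance = 1e-12)
  expect_equal(con$allowable_moment, 35.3e6 * con$W, tolerance = 1e-12)
})
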