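# Shared fixtures: the field-measured mean parameter set and a few derived
# constants used across test files. Everything is built in code from the
# packaged parameter fixture.

hs_params <- honeysuckle_params()
hs_branch <- default_branch(hs_params)
hs_sys <- function(zeta = 0) default_system(hs_params, zeta = zeta)

AS_REF <- 0.039 # reference branch amplitude, m

# Least-squares projection of a sampled signal onto {1, sin(w t), cos(w t)};
# used when checking harmonic-balance residuals.
project_harmonics <- function(t, y, omega) {
  X <- cbind(1, sin(omega * t), cos(omega * t))
  qr.solve(X, y)
}
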