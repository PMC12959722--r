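# stemshake

Mechanics of berry detachment during vibratory harvesting, for Blue
Honeysuckle (*Lonicera caerulea* L.) and similar soft fruit. The package is
aimed at agricultural-engineering researchers designing or tuning shaker
harvesters who want the detachment physics — not just field regressions —
behind the choice of excitation frequency and amplitude.

## The model

The fruit-bearing branch is a **uniform-strength tapered cantilever**
(diameter law `d(z) ∝ z^(2/3)`); its forced bending vibration has a
power-series steady state `f(z,t) = sin(ωt) Σ b_k (z−z1)^((8k+4)/3)` with
`b0 = 9πF/2Eβ²`, where `β` is the section proportionality coefficient fixed
by the measured end diameters.

Each fruit plus stem is a **torsional pendulum** (stiffness `K = EπD⁴/64l`,
inertia `J = I + ma²`) riding on the oscillating branch. Its steady state is
solved by harmonic balance for three stem orientations relative to the
excitation direction:

- **perpendicular** (stem vertical, excitation horizontal): direct forcing,
  amplitude `maω²As / √((K−Jω²)² + (μω)²)`;
- **parallel** (stem horizontal): gravity sets a constant offset
  `θ0 = 2mgaD / (2DK − P²(K−Jω²))` with `P = maω²As`,
  `D = (K−Jω²)² + μ²ω²`, and the excitation enters parametrically — the
  offset diverges (parametric instability) when the denominator changes
  sign;
- **small-angle**: parallel plus an inclination δ; larger offset, same
  instability condition.

Detachment happens by **stress failure** (axial stress `FT/S` or bending
stress `M/W` exceeding the stem's allowable stress) or by **parametric
instability** (zero-damping band `ω0√(χ(√(χ²+2)−χ)) … ω0`,
`χ = J/maAs`). An independent ODE/Floquet oracle (deSolve) cross-checks
every closed form, and a seeded synthetic-orchard simulator emulates
harvest-efficiency (`k1 = 100·m1/(m1+m2)`) and damage-ratio
(`k2 = 100·m3/m1`) trends across frequency, amplitude and stem-orientation
cohorts.

## Worked example

```r
library(stemshake)

sys <- default_system(zeta = 0.1)   # field-measured means, damping ratio 0.1
sys
#> <stem_fruit_system>
#>   K      = 0.002665 N*m/rad
#>   J      = 2.482e-07 kg*m^2
#>   a      = 0.0164 m
#>   zeta   = 0.1
#>   omega0 = 103.6 rad/s

zero_damping_band(sys, 0.039)       # parametric instability band at 39 mm
#>  omega_lo  omega_hi
#>  70.74475 103.61421

detachment_verdict(sys, excitation(30.1, 0.039, "perpendicular"))[
  , c("omega_rad_s", "M_max_Nm", "sigma_bending_Pa", "mechanism")]
#>   omega_rad_s M_max_Nm sigma_bending_Pa mechanism
#> 1        30.1 0.000544        37238634. stress_failure

compare_orientation_cohorts(c(31.42, 52.33, 73.27), 0.039, seed = 1, n = 500)
#>            policy test_no omega_rad_s amplitude_m k1_pct k2_pct
#> 1   vertical_cone       1       31.42       0.039  51.01 0.0000
#> 2   vertical_cone       2       52.33       0.039  86.80 0.1708
#> 3   vertical_cone       3       73.27       0.039  97.77 4.9952
#> 4 horizontal_cone       1       31.42       0.039  24.97 0.0000
#> 5 horizontal_cone       2       52.33       0.039  54.02 0.0000
#> 6 horizontal_cone       3       73.27       0.039  71.72 3.9354
```

Reading the output: the natural frequency of the mean fruit-stem pendulum
is 103.6 rad/s; at a 39 mm branch amplitude the zero-damping parametric
instability band spans ≈70.7–103.6 rad/s. A vertically hanging stem
(perpendicular to the horizontal excitation) already fails in bending at
30.1 rad/s — its maximum moment, 5.4e-4 N·m, exceeds the allowable
5.2e-4 N·m — which is why the vertical-stem cohort out-harvests the
horizontal-stem cohort at every frequency in the simulated orchard (51% vs
25% at the lowest setting), and why efficiency climbs toward ≈100% as the
frequency enters the instability band. The damage ratio stays in single
digits and rises with the peak fruit velocity `As·ω`.

Plots: `autoplot()` methods exist for `stem_sweep()` and `stability_map()`
results, `plot_harvest_sweep()` for harvest tables; `tidy()`/`glance()`
return tibbles from every result object.

A command-line interface (`exec/stemshake`) exposes the sweeps
(`branch-sweep`, `stem-sweep`, `stability-map`, `loads-sweep`,
`oracle-compare`, `harvest-sim`) with explicit frequency units
(`--omega 300rpm,31.42rad/s`) and writes CSV/JSON artifacts.

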