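---
title: "Dynamics of berry fruit-stem systems under vibratory harvesting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of berry fruit-stem systems under vibratory harvesting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemshake)
```

## The problem

Blue Honeysuckle (*Lonicera caerulea* L.) is harvested by shaking: a
machine drives the fruit-bearing branches into oscillation and the berries
detach when their stems fail. Whether and when a berry detaches depends
strongly on the orientation of its stem relative to the excitation
direction. `stemshake` implements a mechanistic model of this process with
three layers:

1. a **branch model** — the fruit-bearing branch as a uniform-strength
   tapered cantilever, with a power-series solution of its forced bending
   vibration;
2. a **stem model** — the fruit plus its stem as a torsional pendulum on
   the oscillating branch, solved by harmonic balance for three stem
   orientations, with a parametric-instability analysis and load/stress
   detachment criteria;
3. a **harvest simulator** — a seeded synthetic orchard with per-fruit
   parameter variability, used to emulate field-trial efficiency and
   damage trends.

An independent ODE/Floquet oracle cross-checks the closed forms throughout.

## Branch model

The branch is assumed to grow as a beam of uniform strength: under a
distributed load $q$ every cross-section sees the same maximum bending
stress $\sigma$, which forces the diameter law
$d(z) = (16q/\pi\sigma)^{1/3} z^{2/3}$ with $z$ measured from the tip.
The cross-section area is then $A(z) = \beta z^{4/3}$ and the second moment
$I_s(z) = A(z)^2/4\pi$, with $\beta$ the *section proportionality
coefficient* fixed by the measured end diameters and branch length through
$A_\mathrm{tip} = \beta z_1^{4/3}$, $A_\mathrm{root} = \beta z_2^{4/3}$,
$z_2 - z_1 = L$. Elimination gives the closed form
$z_2/z_1 = (A_\mathrm{root}/A_\mathrm{tip})^{3/4}$, so no iteration is
needed; a root-finding route is kept as a test oracle.

The steady-state bending deflection under tip-normal harmonic forcing
$F\sin\omega t$ is a power series
$f(z,t) = \sin\omega t\,\sum_k b_k (z-z_1)^{(8k+4)/3}$ with
$b_0 = 9\pi F / 2E\beta^2$. The recurrence for the higher coefficients was
re-derived from scratch by substituting the series into the
variable-section beam equation in the shifted coordinate $x = z - z_1$:
the stiffness term of order $k+1$ balances the inertia term of order $k$,
giving

$$b_{k+1} = b_k \cdot \frac{4\pi\rho\omega^2}{E\beta}\cdot
\frac{81}{(8k+12)(8k+9)(8k+14)(8k+11)}.$$

The $k=1$ coefficient reduces to $27\pi^2 F\rho\omega^2/(308E^2\beta^3)$,
which anchors the derivation. A test substitutes the truncated series back
into the operator with independent power-rule algebra and verifies the
residual equals exactly the unbalanced inertia term of the last retained
coefficient.

Two modelling caveats are worth stating plainly:

* The coordinate system is internally tense: the diameter law measures $z$
  from the tip while the series solution is clamped at the apical
  coordinate $z_1$ of the section system. We implement the series exactly
  as the formulas state (powers of $z - z_1$, clamp at $z_1$) and expose
  the offset; the profile and the series are used for different outputs,
  so the tension is documented rather than resolved.
* The one-term amplitude envelope $A_s(z) = b_0 (z-z_1)^{4/3}$ is a genuine
  low-frequency approximation only. The second-to-first term ratio is
  $3\pi\rho\omega^2 x^{8/3} / 154 E\beta$, which reaches ≈12% at the branch
  root at 31.42 rad/s (the lowest field excitation setting) and falls below
  1% only under ≈9 rad/s. Downstream stem computations therefore use the
  *machine* amplitude (39 mm or 53 mm) directly, not the series envelope.

Truncation defaults to `k_max = 8` with a warning when the last retained
term contributes more than 1e-10 of the sum, and an error when the term
ratio reaches 1 (non-convergent evaluation point).

## Stem model

The fruit plus stem is a rigid pendulum connected to the branch through a
torsional spring of stiffness $K = E\,(\pi d^4/64)/l$ (the stem as a short
cantilever) and viscous damping $\mu$, riding on the branch whose
attachment point oscillates as $A_s\sin\omega t$. The pendulum inertia
about the attachment is $J = I + ma^2$.

**Reconstructed quantities.** The lever arm $a$ and fruit inertia $I$ are
not field-measured. The fruit is idealised as a uniform ellipsoid with
semi-axes $L_f/2$ and $W_f/2$, giving $a = l + L_f/2$ and
$I = (m/5)\left((W_f/2)^2 + (L_f/2)^2\right)$. This is the simplest
choice consistent with the system's measured natural frequency
($\sqrt{K/J} \approx 103.6$ rad/s from the mean parameters); it is a
reconstruction, and users with measured inertias should supply their own.
Gravity defaults to 9.81 m/s². Damping is parameterised by the ratio
$\zeta = \mu/2\sqrt{KJ}$ by default, with $\mu$ derived.

Three orientation cases of the stem relative to the (horizontal)
excitation direction are solved by harmonic balance — a constant offset
plus a fundamental-frequency sinusoid, higher harmonics neglected:

* **perpendicular** (stem hanging vertically): direct forcing; pure
  fundamental with amplitude
  $m a\omega^2 A_s/\sqrt{(K-J\omega^2)^2 + (\mu\omega)^2}$. The gravity
  restoring term is dropped in this case's derivation, and the ODE oracle
  offers the same truncation (`gravity = "none"`) so comparisons isolate
  the harmonic-balance error.
* **parallel** (stem horizontal, along the excitation): gravity sets a
  constant droop $\theta_0$ and the excitation enters *parametrically*
  (multiplying the state). With $D = (K-J\omega^2)^2 + \mu^2\omega^2$ and
  $P = ma\omega^2 A_s$:
  $\theta_0 = 2mgaD / (2DK - P^2(K-J\omega^2))$.
* **small-angle**: parallel plus an inclination $\delta$, which adds a
  direct forcing term; the offset grows with $\delta$ below resonance and
  the instability condition is unchanged.

The phase lag $\arctan(\mu\omega/(K-J\omega^2))$ is implemented with the
two-argument arctangent so the phase stays in $(0,\pi)$ for $\mu>0$ and
the amplitude remains positive and continuous across resonance.

When the offset denominator $2DK - P^2(K-J\omega^2)$ is non-positive the
balance has no bounded solution: the response is *flagged* unstable
(`stable = FALSE`, angles `NA`) rather than raising an error, so frequency
sweeps can cross the unstable band without aborting.

## Parametric instability

The instability boundary is the zero set of $2DK - P^2(K-J\omega^2)$. At
zero damping the band has closed-form edges: with
$\chi = J/(maA_s)$, the lower edge is
$\omega_{lo} = \omega_0\sqrt{\chi(\sqrt{\chi^2+2}-\chi)}$ (implemented in
the cancellation-safe form $2\chi/(\sqrt{\chi^2+2}+\chi)$) and the upper
edge is the natural frequency $\omega_0$. For the mean parameter set at
$A_s = 39$ mm the band is ≈70.7–103.6 rad/s. The boundary damping ratio at
a given frequency follows from the same condition; its maximum over
frequency — the *critical damping ratio* above which no frequency is
unstable — is located by a deterministic 2000-point log-spaced scan on
$[1, 2\omega_0]$ refined by `optimize()`, giving $\zeta^* \approx 0.311$
(reported values near 0.31–0.32 differ only in the rounding of the inputs).

**Validity limit, stated honestly.** The harmonic-balance criterion keeps
only the principal parametric balance. At the study amplitude the
modulation index $q = maA_s/2J \approx 1.11$ — the parametric stiffness
modulation *exceeds* the mean stiffness above ≈64 rad/s — and the exact
stability chart (Floquet multipliers of the linearized equation, computed
by the oracle and validated against the classical Mathieu chart) develops
structure the first-harmonic criterion cannot represent: a secondary
unstable tongue just below the analytic band edge, and continued
instability above $\omega_0$ at damping ratios up to ≈0.2. The two
classifications agree in the band interior and in the far sub-band field;
near and beyond the edges the analytic criterion should be read as the
paper's design rule, not as the exact chart. The package ships both: the
analytic predicate (`is_unstable()`) and the exact classification
(`floquet_classify()`).

## Loads and detachment

The stem detaches the fruit when either the maximum axial stress
$F_{T,\max}/S$ or the maximum bending stress $M_\max/W$ exceeds the
allowable stress ($S = \pi d^2/4$, $W = \pi d^3/32$). The two envelopes
peak at different phase instants, so the criteria are evaluated
*separately*, as the source analysis does; the combined stress is reported
but not used for the verdict. Each printed envelope keeps or drops the
small terms exactly as derived (the weight term is kept in the
perpendicular axial force; the gravity moment is dropped in the bending
envelopes). In the parallel and small-angle configurations a third
mechanism exists: parametric instability, which overrides the stress
verdict whenever the balance diverges.

For the mean parameter set at 39 mm: the perpendicular bending moment
crosses the allowable moment (≈5.16e-4 N·m) at ≈29.4 rad/s and reaches
≈5.44e-4 N·m at 30.1 rad/s, insensitive to the damping ratio over
[0.05, 0.2]; the parallel moment at $\zeta = 0.40$ exceeds the allowable
near 73.5–75.2 rad/s; and at low damping the swelling parallel moment
envelope breaches the allowable slightly *before* the instability boundary
(onset ≈65 rad/s at $\zeta = 0.05$), so the minimum-detachment-frequency
search reports the stress onset there.

## The ODE/Floquet oracle

`integrate_stem()` integrates the full nonlinear pendulum equation
(adaptive `lsoda`, tolerances 1e-10/1e-12, rest initial state — fully
deterministic); `extract_steady_state()` measures the offset, fundamental
amplitude and envelope growth rate from the final cycles;
`floquet_classify()` forms the monodromy matrix of the linearized
parametric equation about the static reference (the gravity droop root for
the parallel/small-angle cases) and classifies stability by multiplier
magnitudes with a 1e-8 collar.

The oracle quantifies the harmonic-balance truncation error honestly: at
small modulation the closed forms agree with the integrated steady state
to well under 1% in offset and ≈2% in amplitude; at the full study
amplitude near the band ($A_s = 39$ mm, 75.2 rad/s, $\zeta = 0.40$) the
neglected higher harmonics shift the true mean angle ≈23% below the
balance value (integrating the linearized equation itself reproduces the
shifted value, so trigonometric nonlinearity contributes almost nothing).
Closed-form users should treat offset predictions at modulation indices
near or above 1 as order-of-magnitude.

## Synthetic orchard

`sample_orchard()` draws per-fruit parameters as independent truncated
normals (mean ± 3 SD, positive) around the packaged field statistics, an
orientation from one of three policies, and per-fruit nuisance quantities
the field never measured:

* **damping ratio**: log-uniform on [0.02, 0.2] — stems exhibit very low
  damping, and the log-uniform spread covers the decade without favouring
  either end;
* **damage threshold**: detached fruit are damaged when their peak
  velocity $v = A_s\omega$ exceeds a per-fruit threshold drawn lognormally
  around 4.3 m/s (sdlog 0.25). The centre was calibrated once so that
  ≈5% of detached fruit are damaged at (73.27 rad/s, 39 mm) — the
  single-digit damage regime reported for that setting — and is then held
  fixed across all conditions; only damage *trends* (rising with amplitude
  and frequency) are meaningful.

Orientation geometry: the excitation is horizontal, so a vertically
hanging stem is the perpendicular case and a horizontal stem the parallel
case; angles are measured from the vertical. Within π/12 of the pure
configurations the corresponding closed form is used (near-parallel stems
get the small-angle solution with the measured $\delta$); in between, the
stress envelopes are interpolated linearly in angle between the two pure
cases, and the instability criterion applies through the parallel-side
component (it is independent of $\delta$). A vectorized fast path computes
per-fruit verdicts for large ensembles; a unit test holds it equal to the
scalar public-API route.

The harvest metrics are the mass fractions
$k_1 = 100\,m_1/(m_1+m_2)$ (efficiency) and $k_2 = 100\,m_3/m_1$ (damage
ratio). What the emulation reproduces from the field trials is the
*directions*: efficiency rising with frequency and amplitude, damage
rising with amplitude, and vertical-stem cohorts out-harvesting
horizontal-stem cohorts at every frequency. What it cannot reproduce —
deliberately — are absolute field efficiencies: transient impact
detachment (which detaches many fruits at low frequency in the field),
canopy position, foliage occlusion and ripeness spread are not modelled,
so emulated efficiencies at the lowest frequencies under-predict the
field tables.

## Problem sizes and determinism

All closed-form checks run on scalars or small grids. The test-suite
ensembles use 300–500 fruits per cohort (10 seeds for the
monotonicity-in-expectation check), sizes at which the Monte Carlo error
of $k_1$ is ≈1–2 percentage points — comfortably below the ≈20-point
orientation effect being asserted. Every stochastic path flows from a
single integer seed; identical seeds reproduce samples, tables and CSV
outputs byte for byte.

## Known limitations

* $a$ and $I$ are reconstructed (ellipsoid fruit), not measured.
* The analytic instability criterion is first-harmonic only; at the study
  amplitude the true chart is wider (see above).
* Harmonic-balance offsets degrade at modulation indices ≳ 1.
* No transient/impact detachment, no out-of-phase or higher fruit motion
  modes (flapping, rotation, torsion), no branch damping, no multi-branch
  topology, no shear or fatigue stress in the stem.
* The bulk fruit density in the parameter file is recorded but unused:
  mass is measured directly.
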