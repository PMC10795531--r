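---
title: "Methods: the coupled AR–BMP ADM1 simulator"
author: "adm1sim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled AR-BMP ADM1 simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`adm1sim` implements the BSM2 parameterization of the IWA Anaerobic
Digestion Model No. 1. The liquid phase carries 24 "core" components —
twelve solubles (monosaccharides S_su through dissolved methane S_ch4,
inorganic carbon S_IC, inorganic nitrogen S_IN, soluble inerts S_I) and
twelve particulates (composites X_c, the three hydrolysis substrates, seven
biomass groups, particulate inerts X_I) — plus the strong-ion pools S_cat
and S_an, six weak acid/base ion states, and a headspace with H₂, CH₄, CO₂
and an inert flush gas.

Nineteen biochemical processes act on the core components through a Petersen
matrix built at run time from the parameter set (`petersen_matrix()`). The
inorganic-carbon and inorganic-nitrogen columns are not transcribed
constants: they are computed as the negatives of the carbon- and
nitrogen-weighted row sums, so every process closes its C and N balance
*exactly* for any parameter set that itself closes the disintegration
balance (the packaged set does; `validate_parameters()` enforces it). COD
closure of every row is a structural identity and is tested.

Kinetics follow the standard BSM2 wiring: first-order disintegration and
hydrolysis; Monod uptake with the acidogenic/acetogenic pH switch and
nitrogen limitation on all uptakes, hydrogen inhibition on the LCFA, C4 and
propionate oxidizers, and the acetate-specific pH switch plus free-ammonia
inhibition on acetoclastic methanogenesis; shared C4 biomass splits between
valerate and butyrate in proportion to substrate. Gas-liquid transfer is
two-film with the COD-per-mole factors 16 (H₂) and 64 (CH₄); CO₂ transfers
on a mole basis from the undissociated fraction `S_IC - S_hco3`. Headspace
outflow is the linear overpressure law `q_gas = k_p (P_gas - P_atm)`,
floored at zero.

### DAE and ODE formulations

The fast acid/base reactions can be treated two ways, selected per run:

* **DAE** (default): the six ion states and the hydrogen-ion activity are
  algebraic. At every derivative evaluation the charge balance is solved
  for `S_H+` by a safeguarded Newton iteration (analytic gradient,
  bisection fallback on `[1e-14, 1]` M, warm-started from the previous
  step, residual tolerance 1e-12 M). The balance is monotone in `S_H+`, so
  the root is unique.
* **ODE**: the ion states integrate as stiff kinetics with the `k_AB`
  rates (1e10 M⁻¹ d⁻¹) and `S_H+` comes from the closed-form quadratic of
  the ion-state charge balance.

Both formulations must and do agree at steady state within far better than
1% on every component; the test suite asserts this along a batch trajectory
and at the continuous steady state. The DAE form is roughly an order of
magnitude faster and is used everywhere by default.

### Numerical choices

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`,
maximum step 0.1 d. Small negative excursions (below ~1e-10) that a stiff
integrator can produce are clamped to zero inside rate laws only, never in
the state itself; trajectories are asserted non-negative beyond 1e-8.
Steady state is declared when no concentration changes by more than 0.1%
(relative, floor 1e-6) over the trailing 10 d, with a 90 d minimum and
extension in 30 d blocks up to 10× the nominal duration. The derivative
function used by the integrator is an inlined scalar-indexed version of the
modular kinetics API; the two are asserted equal to 1e-10 relative on
randomized states, so the readable path is the specification of the fast
path.

## Reactor stages and their conventions

**Continuous AR.** Defaults: V_liq = 3485.4 m³, V_gas = 300 m³,
Q = 246.67 m³/d (the parameter table prints this flow with a stray leading
character; it is read as 246.67 and logged in every run manifest). The
packaged parameter table also lists a 40 d additional solids retention, but
the reference steady-state composition the package reproduces (X_c ≈ 5.0,
X_I ≈ 7.5 kg COD/m³) is only consistent with purely hydraulic particulate
retention — with 40 extra days the inert particulate balance alone gives
X_I ≈ 30. The baseline configuration therefore uses `tresX = 0`; `tresX`
remains a configuration field and enters the stratified removal rate.

**Batch BMP.** The batch stage runs per m³ of liquid with a 1.5
headspace-to-liquid ratio (the bench assay uses 100 mL working volume in a
250 mL bottle) and is scaled to assay volume only in the output conversion
(0.350 Nm³ CH₄ per kg COD, divided by the VS mass, default
0.1 L × 1.1% = 1.1 g). The headspace starts as an inert (nitrogen) flush at
atmospheric pressure with product-gas partials at 1e-5 bar, so only
digestion-generated overpressure drives outflow. Two cumulative curves are
carried: the liquid-to-gas transfer integral (the reported methane
production) and the vessel-outflow integral, which lags it by the headspace
holdup. pH/H₂/NH₃ inhibition is off by default in the batch stage — the
assay is temperature-controlled and buffered — while nitrogen limitation
always applies; both settings are a config flag and the suite exercises
both.

**Coupling.** `couple_ar_bmp()` seeds the batch with the AR steady-state
liquid composition unchanged except that dissolved H₂ and CH₄ are zeroed:
the nitrogen purge of the assay strips dissolved product gas, and the
reference seed composition lists both as zero. Without degassing the
reactor's dissolved methane appears as a spurious instant ~1.8 mL/g VS
offset across the whole curve.

**Stratification.** `chi = V_p/V - 1` and `kappa = (V - V_s)/(V_p - V)`
re-parameterize the particulate and solute effective volumes:
`V_p = V(1 + chi)`, `V_s = V(1 - kappa chi)` (feasible while
`kappa·chi < 1`). Solubles dilute at `Q/V_s`; particulates are removed at
`1/(tresX + V_p/Q)`; the biochemical volume stays V_liq. This is the only
reading of "effective volume" consistent with selectively increased
particle residence. Sweeps run on the uninhibited model by default: the
reference analysis reports a smooth unimodal production curve up to its
optimum, which is the behavior of a well-buffered digester whose pH
switches stay at 1. Under the standard physicochemistry with inhibition
enabled, the default influent (strong-anion pool 0.10 M) loses soluble
buffering as `V_s` shrinks and acidifies at moderate chi — a real failure
mode worth studying, but a different experiment; it is available by passing
an inhibited base configuration.

## The inverse problem

`calibrate_influent()` minimizes `S = Σ r_i²/σ_m,i` with
`r_i = y_i − f(x_i, Π)` over daily cumulative yields, plus an optional
weighted residual pulling the reactor-output total COD toward its measured
value (a soft constraint rather than a hard one, since the combination of
the two data sources is otherwise unspecified). The σ-power in the
denominator is deliberately 1 — matching the printed form of the source
formulation — with classical inverse-variance weighting (`σ²`) available
by flag; the form used is recorded in the result.

The optimizer is DE/rand/1/bin: mutant `v = x_r1 + F(x_r2 − x_r3)` over
distinct random members, binomial crossover with one forced dimension,
reflection (not clipping) at the bounds, greedy selection; termination when
the population objective spread drops below 4e-3 or at the generation cap.
Defaults NP = 15·dim, F = 0.8, CR = 0.9, 200 generations; every run takes
an explicit seed and restarts use consecutive seeds, reporting the
cross-restart parameter spread. Forward-model failures return a 1e6
penalty with the cause attached, so the population can step around
pathological parameter vectors.

The default free-parameter set is {X_c, X_pr, X_li, X_I influent, Q}: the
starred influent entries plus the starred flow. These are not jointly
identifiable from one mean curve and one COD value — several compositions
produce near-identical methane curves — so the package's recovery
contract, and its tests, are on the fitted curve and the output COD, not
on the parameter vector itself.

## The synthetic-data generator

`generate_synthetic_bmp()` emulates the replicate structure of the bench
assay: the coupled model's daily NmL curve plus independent Gaussian noise
per replicate-day (default sd 3 NmL, six replicates, the reference
replicate spread), day 0 pinned at zero, and per-replicate monotonicity
enforced by cumulative maximum, as a volume-displacement reading cannot
decrease. The clamp means the empirical replicate sd matches the nominal
noise only where daily increments dominate the noise (the rising limb); on
the plateau it shrinks the spread, exactly as clipping would in a real
logger. What the generator does *not* emulate: lag phases from inoculum
adaptation, temperature excursions, leak-driven losses, CO₂ scrub
breakthrough, or between-replicate systematic offsets. Recovery tests
passing on this generator therefore demonstrate the inverse machinery, not
robustness to those real-data pathologies.

## Problem sizes used by the tests and the acceptance script

Chosen to keep a full run interactive: the continuous stage integrates 90 d
(extending until the steady-state window passes, typically ≤ 120 d); the
batch stage 11 d on a 0.1 d output grid; stratification sweeps use a
0.04-step coarse pass refined to 0.01 around each optimum
(~230 steady-state runs over kappa 0.8–1.5, warm-started); calibration
tests recover one influent parameter with NP = 6 and ≤ 12 generations on a
60 d forward model. A handful of extreme-chi sweep points (kappa·chi close
to 1) exceed the stiff-step budget and are reported as non-converged rows
rather than silently dropped.

## Known limitations

* The reference output composition cannot be reproduced in its inorganic
  pools: its printed S_IC (0.64 M) is not reconcilable with Henry
  equilibrium plus charge balance under the stated ion pools, and its
  protein/amino-acid-consumer levels imply more influent protein than the
  printed influent carries. The package's self-consistent steady state
  matches the printed organics (composites, inerts) within a few percent
  and computes its own S_IC (~0.04 M, pH ≈ 6.7).
* Temperature is fixed at T_op; all equilibrium and Henry constants are
  used exactly as tabulated (already evaluated at 308.15 K), with no van't
  Hoff recomputation.
* No sulfate reduction, precipitation, trace elements, or spatial
  (hydrodynamic) structure; chi/kappa stand in for flow-pattern effects
  without claiming a CFD justification.
* The inhibited digester is bistable; start-up from a strongly
  under-seeded inoculum acidifies and dies. Steady-state claims hold
  within the operating basin.
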