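# adm1sim

Coupled anaerobic-reactor and BMP-assay simulation with the ADM1/BSM2 model,
for wastewater and bioenergy engineers who want to characterize sewage sludge
and its methane potential from routinely measured quantities (total COD and a
bench-scale biochemical methane potential curve) instead of a full influent
fractionation.

## What it does

The package implements the Benchmark Simulation Model 2 (BSM2) variant of the
IWA Anaerobic Digestion Model No. 1 as a two-stage simulator:

1. **AR stage** — a continuous stirred-tank anaerobic reactor (CSTR)
   integrating the full 35-variable ADM1 system: first-order disintegration
   of composites (`rho_1 = k_dis X_c`) and hydrolysis of carbohydrates,
   proteins and lipids; Monod substrate uptake
   `rho_j = k_m,j S_j/(K_S,j + S_j) X_j I_j` for the eight trophic groups
   with pH, hydrogen and free-ammonia inhibition
   (`I_pH = exp(-3 ((pH - pH_UL)/(pH_UL - pH_LL))^2)` below `pH_UL`,
   `I_h2 = 1/(1 + S_h2/K_I)`, nitrogen limitation `S_IN/(S_IN + K_S_IN)`);
   acid-base chemistry either as algebraic equilibrium constraints with a
   charge-balance root solve for `S_H+` (DAE form) or as stiff `k_AB`
   kinetics (ODE form); Henry-law gas-liquid transfer and an overpressure
   headspace outflow `q_gas = k_p (P_gas - P_atm)`.
2. **BMP stage** — the reactor's steady-state output seeds a batch digestion
   emulating a 100 mL, 37 °C BMP assay; cumulative methane is converted at
   0.350 Nm³ CH₄ per kg COD and normalized per gram of volatile solids.

On top of the forward model:

* **Influent calibration** (`calibrate_influent()`) — recovers the influent
  sludge composition (X_c, X_pr, X_li, X_I, optionally flow) by minimizing
  the weighted least-squares mismatch `S = Σ r_i²/σ_m,i` between the
  simulated coupled methane curve (plus reactor-output COD) and
  measurements, with a DE/rand/1/bin differential-evolution optimizer
  written for the purpose (spread tolerance 4e-3, seed-reproducible).
* **Residence-time stratification** (`optimize_stratification()`) — sweeps
  the dimensionless parameters `chi = V_p/V - 1` and
  `kappa = (V - V_s)/(V_p - V)` (particulate and solute effective volumes)
  and locates the chi that maximizes steady-state methane production per m³
  of influent for each kappa.
* **BMP data handling** (`bmp_dataset()`, `bmp_summary()`,
  `generate_synthetic_bmp()`) — replicate curve ingestion, per-day
  mean/sd/se, yields per VS and per COD removed, and a synthetic replicate
  generator with Gaussian noise for testing the inverse machinery.

## Worked example

```r
library(adm1sim)

p   <- adm1_parameters()        # full BSM2 constant set, calibrated entries
sim <- couple_ar_bmp(adm1_influent(), p = p)

sim$ar$final_state[["X_c"]]     # 5.1899  kg COD/m3 composites at steady state
sim$ar$final_state[["S_I"]]     # 3.6866  soluble inerts
sim$ar$final_state[["X_I"]]     # 7.4202  particulate inerts
total_cod(sim$ar$final_state, dissolved_gas = FALSE)  # 20.68 kg COD/m3

curve <- cumulative_methane(sim$bmp, vs_mass = 1.1, working_volume = 0.1)
curve$ml_per_gvs[curve$time == 1]    # 46.54  mL CH4/g VS after one day
curve$ml_per_gvs[curve$time == 11]   # 125.95 mL CH4/g VS at assay end
```

The simulated day-1 and day-11 yields sit within 1% of the package's
reference simulated curve and within 3.6% of the measured mean curve of the
reference assay (`bmp_reference_curve()`), whose six replicates averaged
136 NmL (124 mL CH₄/g VS).

Stratification study (a few minutes: tens of steady-state runs):

```r
tab <- optimize_stratification(adm1_influent(), p = p,
                               kappa_list = c(0.8, 1.0))
tab
#   kappa chi_opt production increment_pct converged
#     0.8    0.88      30.19          5.41      TRUE
#     1.0    0.68      29.91          4.41      TRUE
```

Selective particulate retention (chi = 0.68 at kappa = 1) raises methane
production per m³ of influent by ~4.4% over the unmodified reactor; the best
setting over the studied grid (kappa = 0.8, chi = 0.88) gains ~5.4%.

## Command-line use

A thin CLI over the same functions ships in `inst/scripts/adm1`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","adm1",package="adm1sim"))')" \
  couple --out results/
```

Commands: `simulate-ar`, `simulate-bmp`, `couple`, `calibrate`,
`optimize-stratification`. Every run writes result CSVs, a JSON summary and
a manifest with the fully resolved configuration; identical configuration
and seed give byte-identical outputs.
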