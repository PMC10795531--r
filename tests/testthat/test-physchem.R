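test_that("pure-water charge balance gives sqrt(K_w)", {
  p <- default_params()
  S_H <- solve_hydrogen_ion(adm1_state(), p)
  expect_equal(S_H, sqrt(p$K_h2o), tolerance = 1e-5)
  expect_equal(-log10(S_H), 6.84, tolerance = 1e-2)
})

test_that("equal strong-ion increments leave the root unchanged", {
  p <- default_params()
  base <- adm1_state(S_IC = 0.1, S_IN = 0.1, S_ac = 0.04,
                     S_cat = 0.04, S_an = 0.10)
  bumped <- base
  bumped[["S_cat"]] <- base[["S_cat"]] + 0.013
  bumped[["S_an"]] <- base[["S_an"]] + 0.013
  expect_equal(solve_hydrogen_ion(base, p), solve_hydrogen_ion(bumped, p),
               tolerance = 1e-9)
})

test_that("root matches a fine-grid bisection oracle on a sludge state", {
  p <- default_params()
  st <- ar_reference_output()
  residual <- function(S_H) {
    ion <- ion_concentrations(st, S_H, p)
    st[["S_cat"]] + (st[["S_IN"]] - ion[["S_nh3"]]) + S_H -
      ion[["S_hco3_ion"]] - ion[["S_ac_ion"]] / 64 -
      ion[["S_pro_ion"]] / 112 - ion[["S_bu_ion"]] / 160 -
      ion[["S_va_ion"]] / 208 - p$K_h2o / S_H - st[["S_an"]]
  }
  lo <- 1e-14; hi <- 1
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (residual(mid) > 0) hi <- mid else lo <- mid
  }
  S_H <- solve_hydrogen_ion(st, p)
  expect_equal(S_H, sqrt(lo * hi), tolerance = 1e-8)
  expect_lt(abs(residual(S_H)), 1e-12)
  ## the buffered reference sludge sits in the measured pH band
  expect_gt(-log10(S_H), 4.5)
  expect_lt(-log10(S_H), 8.5)
})

test_that("ion equilibria vanish at equilibrium and scale by k_AB", {
  p <- default_params()
  st <- adm1_state(S_ac = 0.2, S_IC = 0.15, S_IN = 0.1, S_va = 0.01,
                   S_bu = 0.01, S_pro = 0.02, S_cat = 0.04, S_an = 0.02)
  S_H <- solve_hydrogen_ion(st, p)
  st[adm1_state_names("ions")] <- ion_concentrations(st, S_H, p)
  resid <- ion_equilibria(st, S_H, p, mode = "dae")
  expect_lt(max(abs(resid)), 1e-12)
  ## off equilibrium, ODE rates are the residuals scaled by k_AB
  st[["S_ac_ion"]] <- st[["S_ac_ion"]] * 0.9
  expect_equal(ion_equilibria(st, S_H, p, "ode")[["ac"]],
               p$k_AB_ac * ion_equilibria(st, S_H, p, "dae")[["ac"]])
  ## half-dissociation at pK_a
  st2 <- adm1_state(S_IC = 0.2)
  ions <- ion_concentrations(st2, p$K_a_co2, p)
  expect_equal(ions[["S_hco3_ion"]], 0.1)
  ## S_H -> 0 gives full dissociation
  ions0 <- ion_concentrations(st2, 1e-14, p)
  expect_equal(ions0[["S_hco3_ion"]], 0.2, tolerance = 1e-6)
})

test_that("gas transfer obeys equilibrium, sign and linearity contracts", {
  p <- default_params()
  RT <- p$R * p$T_op
  p_ch4 <- 0.6
  eq <- adm1_state(S_ch4 = 64 * p$K_H_ch4 * p_ch4,
                   S_gas_ch4 = 64 * p_ch4 / RT)
  expect_equal(gas_transfer(eq, p)[["rhoT_ch4"]], 0, tolerance = 1e-12)
  super <- eq; super[["S_ch4"]] <- eq[["S_ch4"]] * 2
  sub <- eq; sub[["S_ch4"]] <- eq[["S_ch4"]] / 2
  expect_gt(gas_transfer(super, p)[["rhoT_ch4"]], 0)
  expect_lt(gas_transfer(sub, p)[["rhoT_ch4"]], 0)
  p2 <- adm1_parameters(list(k_L_a = 2 * p$k_L_a))
  expect_equal(gas_transfer(super, p2), 2 * gas_transfer(super, p))
})

test_that("overpressure valve is linear with the configured conductance", {
  p <- default_params()
  RT <- p$R * p$T_op
  at_atm <- adm1_state(S_gas_ch4 = 64 * (p$P_atm - p$p_gas_h2o) / RT)
  expect_equal(gas_flow(at_atm, p)$q_gas, 0)
  over <- adm1_state(S_gas_ch4 = 64 * (p$P_atm + 0.001 - p$p_gas_h2o) / RT)
  expect_equal(gas_flow(over, p)$q_gas, 50, tolerance = 1e-9)
  expect_equal(gas_flow(over, p)$dry_ch4_fraction, 1)
  ## dry fraction splits between product gases
  mix <- adm1_state(S_gas_ch4 = 64 * 0.4 / RT, S_gas_co2 = 0.2 / RT)
  expect_equal(gas_flow(mix, p)$dry_ch4_fraction, 0.4 / 0.6)
})
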