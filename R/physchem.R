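## Acid-base algebra, gas-liquid transfer and headspace flow.
## COD equivalents of the VFA anions (g COD per mole) used to express their
## charge in mole units: acetate 64, propionate 112, butyrate 160,
## valerate 208. Hydrogen is 16 g COD/mole, methane 64 g COD/mole.

.cod_per_mole <- c(va = 208, bu = 160, pro = 112, ac = 64)

## Charge-balance residual and derivative with ion pairs at equilibrium,
## as functions of the hydrogen-ion activity (M).
.charge_balance <- function(S_H, tot, p) {
  frac <- function(K) K / (K + S_H)      # dissociated fraction
  f <- tot$S_cat + tot$S_IN * (S_H / (p$K_a_IN + S_H)) + S_H -
    tot$S_IC * frac(p$K_a_co2) -
    tot$S_ac  * frac(p$K_a_ac)  / 64 -
    tot$S_pro * frac(p$K_a_pro) / 112 -
    tot$S_bu  * frac(p$K_a_bu)  / 160 -
    tot$S_va  * frac(p$K_a_va)  / 208 -
    p$K_h2o / S_H - tot$S_an
  f
}

.charge_balance_grad <- function(S_H, tot, p) {
  dfrac <- function(K) -K / (K + S_H)^2
  tot$S_IN * p$K_a_IN / (p$K_a_IN + S_H)^2 + 1 -
    tot$S_IC * dfrac(p$K_a_co2) -
    tot$S_ac  * dfrac(p$K_a_ac)  / 64 -
    tot$S_pro * dfrac(p$K_a_pro) / 112 -
    tot$S_bu  * dfrac(p$K_a_bu)  / 160 -
    tot$S_va  * dfrac(p$K_a_va)  / 208 +
    p$K_h2o / S_H^2
}

#' Solve the charge balance for the hydrogen-ion activity
#'
#' Finds the unique positive root of the liquid-phase charge balance with all
#' weak acid/base pairs at equilibrium (the algebraic pH closure of the DAE
#' formulation): cations + NH4+ + H+ = HCO3- + VFA anions (in mole units) +
#' OH- + anions. The residual is monotone in `S_H+`, so a safeguarded Newton
#' iteration (with bisection fallback on the bracket `[1e-14, 1]` M) always
#' converges; the iteration can be warm-started from a previous solution.
#'
#' @param state an `adm1_state` or named vector with the total pools
#'   `S_va`, `S_bu`, `S_pro`, `S_ac` (kg COD/m3), `S_IC`, `S_IN`, `S_cat`,
#'   `S_an` (M).
#' @param p an `adm1_parameters` object.
#' @param start optional starting guess for `S_H+` (M).
#' @param tol absolute tolerance on the charge residual (M), default 1e-12.
#' @return `S_H+` in M; `pH = -log10(S_H+)`.
#' @export
#' @examples
#' p <- adm1_parameters()
#' solve_hydrogen_ion(adm1_state(), p)  # pure water: sqrt(K_h2o)
solve_hydrogen_ion <- function(state, p, start = NULL, tol = 1e-12) {
  y <- unclass(state)
  tot <- list(S_va = max(y[["S_va"]], 0), S_bu = max(y[["S_bu"]], 0),
              S_pro = max(y[["S_pro"]], 0), S_ac = max(y[["S_ac"]], 0),
              S_IC = max(y[["S_IC"]], 0), S_IN = max(y[["S_IN"]], 0),
              S_cat = y[["S_cat"]], S_an = y[["S_an"]])
  lo <- 1e-14; hi <- 1
  f_lo <- .charge_balance(lo, tot, p)
  f_hi <- .charge_balance(hi, tot, p)
  if (f_lo > 0 || f_hi < 0)
    stop("charge balance has no positive root in [1e-14, 1] M; state: ",
         paste(sprintf("%s=%.4g", names(tot), unlist(tot)), collapse = ", "),
         call. = FALSE)
  x <- if (!is.null(start) && start > lo && start < hi) start else 1e-7
  for (it in seq_len(100)) {
    fx <- .charge_balance(x, tot, p)
    if (abs(fx) < tol) return(x)
    if (fx > 0) hi <- x else lo <- x
    step <- fx / .charge_balance_grad(x, tot, p)
    x_new <- x - step
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi)
      x_new <- sqrt(lo * hi)  # geometric bisection keeps positivity
    x <- x_new
  }
  x
}

#' Weak acid/base ion concentrations at equilibrium
#'
#' Given the hydrogen-ion activity, returns the equilibrium dissociated
#' concentrations: the four VFA anions (kg COD/m3), bicarbonate (M) and free
#' ammonia (M).
#'
#' @param state an `adm1_state` or named vector of total pools.
#' @param S_H hydrogen-ion activity, M.
#' @param p an `adm1_parameters` object.
#' @return named numeric vector over the six ion states.
#' @export
ion_concentrations <- function(state, S_H, p) {
  y <- unclass(state)
  frac <- function(K) K / (K + S_H)
  c(S_va_ion = max(y[["S_va"]], 0) * frac(p$K_a_va),
    S_bu_ion = max(y[["S_bu"]], 0) * frac(p$K_a_bu),
    S_pro_ion = max(y[["S_pro"]], 0) * frac(p$K_a_pro),
    S_ac_ion = max(y[["S_ac"]], 0) * frac(p$K_a_ac),
    S_hco3_ion = max(y[["S_IC"]], 0) * frac(p$K_a_co2),
    S_nh3 = max(y[["S_IN"]], 0) * frac(p$K_a_IN))
}

#' Acid-base residuals (DAE mode) or kinetic rates (ODE mode)
#'
#' For each weak acid/base pair the equilibrium defect is
#' `S_ion * (K_a + S_H+) - K_a * S_total`. In `"dae"` mode the defects are
#' returned as algebraic residuals; in `"ode"` mode they are scaled by the
#' kinetic acid-base rate constants `k_AB_*` to give the dissociation rates
#' used as stiff kinetics. Both vanish at equilibrium.
#'
#' @param state an `adm1_state` carrying both totals and ion states.
#' @param S_H hydrogen-ion activity, M.
#' @param p an `adm1_parameters` object.
#' @param mode `"dae"` or `"ode"`.
#' @return named vector over the six pairs (order: va, bu, pro, ac, co2, IN).
#' @export
ion_equilibria <- function(state, S_H, p, mode = c("dae", "ode")) {
  mode <- match.arg(mode)
  if (any(c(p$K_a_va, p$K_a_bu, p$K_a_pro, p$K_a_ac, p$K_a_co2, p$K_a_IN) <= 0))
    stop("equilibrium constants must be positive", call. = FALSE)
  y <- unclass(state)
  defect <- c(
    va = y[["S_va_ion"]] * (p$K_a_va + S_H) - p$K_a_va * y[["S_va"]],
    bu = y[["S_bu_ion"]] * (p$K_a_bu + S_H) - p$K_a_bu * y[["S_bu"]],
    pro = y[["S_pro_ion"]] * (p$K_a_pro + S_H) - p$K_a_pro * y[["S_pro"]],
    ac = y[["S_ac_ion"]] * (p$K_a_ac + S_H) - p$K_a_ac * y[["S_ac"]],
    co2 = y[["S_hco3_ion"]] * (p$K_a_co2 + S_H) - p$K_a_co2 * y[["S_IC"]],
    IN = y[["S_nh3"]] * (p$K_a_IN + S_H) - p$K_a_IN * y[["S_IN"]])
  if (mode == "ode")
    defect <- defect * c(p$k_AB_va, p$k_AB_bu, p$k_AB_pro, p$k_AB_ac,
                         p$k_AB_co2, p$k_AB_IN)
  defect
}

#' Headspace partial pressures from gas-phase concentrations
#'
#' Ideal-gas conversion at the operating temperature: hydrogen and methane
#' headspace concentrations are carried in kg COD/m3 (16 and 64 g COD/mole),
#' carbon dioxide and the inert flush gas in kmole/m3.
#'
#' @param state an `adm1_state` or named vector with the gas states.
#' @param p an `adm1_parameters` object.
#' @return named vector `p_h2`, `p_ch4`, `p_co2`, `p_n2` (bar).
#' @export
gas_partial_pressures <- function(state, p) {
  y <- unclass(state)
  RT <- p$R * p$T_op
  c(p_h2 = max(y[["S_gas_h2"]], 0) * RT / 16,
    p_ch4 = max(y[["S_gas_ch4"]], 0) * RT / 64,
    p_co2 = max(y[["S_gas_co2"]], 0) * RT,
    p_n2 = max(y[["S_gas_n2"]], 0) * RT)
}

#' Gas-liquid transfer rates
#'
#' Two-film transfer driven by the departure from Henry equilibrium:
#' `rhoT_i = k_L_a * (S_liq_i - f_i * K_H_i * p_gas_i)` with the COD-per-mole
#' factor `f` equal to 16 for hydrogen, 64 for methane and 1 (mole basis) for
#' carbon dioxide, whose dissolved species is `S_IC - S_hco3-`. Positive
#' rates transfer from liquid to gas.
#'
#' @param state an `adm1_state` with liquid and gas states; `S_hco3_ion`
#'   must be consistent with the pH closure in use.
#' @param p an `adm1_parameters` object.
#' @return named vector `rhoT_h2`, `rhoT_ch4`, `rhoT_co2` (kg COD/m3/d for
#'   H2/CH4, kmole C/m3/d for CO2).
#' @export
gas_transfer <- function(state, p) {
  if (any(c(p$K_H_h2, p$K_H_ch4, p$K_H_co2) <= 0))
    stop("Henry constants must be positive", call. = FALSE)
  y <- unclass(state)
  pp <- gas_partial_pressures(state, p)
  S_co2 <- max(y[["S_IC"]], 0) - max(y[["S_hco3_ion"]], 0)
  c(rhoT_h2 = p$k_L_a * (y[["S_h2"]] - 16 * p$K_H_h2 * pp[["p_h2"]]),
    rhoT_ch4 = p$k_L_a * (y[["S_ch4"]] - 64 * p$K_H_ch4 * pp[["p_ch4"]]),
    rhoT_co2 = p$k_L_a * (S_co2 - p$K_H_co2 * pp[["p_co2"]]))
}

#' Headspace outflow through the overpressure valve
#'
#' Total headspace pressure is the sum of the product-gas partial pressures,
#' water vapour and any inert flush gas; the volumetric outflow is linear in
#' the overpressure, `q_gas = k_p * (P_gas - P_atm)`, floored at zero.
#'
#' @param state an `adm1_state` with the gas states.
#' @param p an `adm1_parameters` object.
#' @return list with `q_gas` (m3/d at headspace conditions), `P_gas` (bar),
#'   partial pressures, and the dry methane fraction
#'   `p_ch4 / (P_gas - p_gas_h2o)`.
#' @export
#' @examples
#' p <- adm1_parameters()
#' st <- adm1_state(S_gas_ch4 = 64 * (p$P_atm + 0.001 - p$p_gas_h2o) /
#'                    (p$R * p$T_op))
#' gas_flow(st, p)$q_gas  # 50 m3/d
gas_flow <- function(state, p) {
  pp <- gas_partial_pressures(state, p)
  P_gas <- sum(pp) + p$p_gas_h2o
  dry <- P_gas - p$p_gas_h2o
  list(q_gas = max(0, p$k_p * (P_gas - p$P_atm)),
       P_gas = P_gas,
       partial_pressures = pp,
       dry_ch4_fraction = if (dry > 0) pp[["p_ch4"]] / dry else 0)
}
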