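## Assembly of the full differential(-algebraic) system.
##
## Integrated variables:
##   dae mode: 24 core + S_cat + S_an + 3 gas + inert gas + 2 CH4 accumulators
##             (ion states and S_H+ are algebraic, solved inside the RHS)
##   ode mode: the same plus the 6 ion states as stiff kinetic variables
##             (S_H+ from the closed-form charge balance over the ion states)

.dae_state_names <- function() c(.core_names, "S_cat", "S_an",
                                 .gas_names, .extra_names)
.ode_state_names <- function() c(.core_names, "S_cat", "S_an", .ion_names,
                                 .gas_names, .extra_names)

#' Right-hand side of the ADM1 reactor system
#'
#' Builds the derivative function of the coupled liquid/gas system for use
#' with a stiff integrator. Liquid balances are
#' `dS/dt = (Q/V_s)(S_in - S) + sum_j nu_ij rho_j` for soluble components and
#' `dX/dt = (Q/V_liq) X_in - X/(tresX + V_p/Q) + sum_j nu_ij rho_j` for
#' particulates, where `V_p = V_liq (1 + chi)` and `V_s = V_liq (1 - kappa
#' chi)` are the stratified effective volumes (both equal to `V_liq` in the
#' unstratified reactor). Gas balances are driven by the transfer rates and
#' the overpressure outflow. In batch mode (`Q = 0`) all transport terms
#' vanish.
#'
#' @param influent an `adm1_state` influent composition (ignored in batch
#'   mode).
#' @param config a `reactor_config`.
#' @param p an `adm1_parameters` object.
#' @param formulation `"dae"` (ion states algebraic) or `"ode"` (ion states
#'   kinetic).
#' @return a function `f(t, y, parms)` in the form expected by
#'   [deSolve::lsoda()], returning the derivatives and, as auxiliaries, pH,
#'   gas flow and the inhibition factors' product range.
#' @export
make_adm1_rhs <- function(influent, config, p,
                          formulation = c("dae", "ode")) {
  formulation <- match.arg(formulation)
  nu <- petersen_matrix(p)
  sol_idx <- 1:12
  part_idx <- 13:24
  nms <- if (formulation == "dae") .dae_state_names() else .ode_state_names()
  n <- length(nms)
  idx <- stats::setNames(seq_len(n), nms)
  y_in <- unclass(influent)[c(.core_names, "S_cat", "S_an")]

  batch <- config$mode == "batch"
  V_liq <- config$V_liq
  V_gas <- config$V_gas
  Q <- if (batch) 0 else config$Q
  vols <- effective_volumes(V_liq, config$chi, config$kappa)
  D_sol <- if (batch) 0 else Q / vols$V_s
  theta_x <- if (batch) 0 else 1 / (config$tresX + vols$V_p / Q)
  inhib_on <- isTRUE(config$inhibition_enabled)
  cache <- new.env(parent = emptyenv())
  cache$S_H <- 1e-7

  function(t, y, parms) {
    names(y) <- nms
    st <- y  # named vector; treated as state

    ## pH closure
    if (formulation == "dae") {
      S_H <- solve_hydrogen_ion(st, p, start = cache$S_H)
      cache$S_H <- S_H
      ions <- ion_concentrations(st, S_H, p)
      st <- c(st, ions)
    } else {
      nh4 <- max(st[["S_IN"]], 0) - max(st[["S_nh3"]], 0)
      theta <- st[["S_cat"]] + nh4 - max(st[["S_hco3_ion"]], 0) -
        max(st[["S_ac_ion"]], 0) / 64 - max(st[["S_pro_ion"]], 0) / 112 -
        max(st[["S_bu_ion"]], 0) / 160 - max(st[["S_va_ion"]], 0) / 208 -
        st[["S_an"]]
      S_H <- -theta / 2 + sqrt(theta^2 + 4 * p$K_h2o) / 2
    }
    pH <- -log10(S_H)

    ## biochemistry
    I <- inhibition_factors(pH, max(st[["S_h2"]], 0), st[["S_nh3"]],
                            max(st[["S_IN"]], 0), p, enabled = inhib_on)
    r <- process_rates(st, I, p)
    dy_bio <- as.vector(crossprod(nu, r))  # 24 core components

    ## gas-liquid exchange
    rhoT <- gas_transfer(st, p)
    dy_bio[8] <- dy_bio[8] - rhoT[["rhoT_h2"]]
    dy_bio[9] <- dy_bio[9] - rhoT[["rhoT_ch4"]]
    dy_bio[10] <- dy_bio[10] - rhoT[["rhoT_co2"]]

    ## transport
    dcore <- dy_bio
    dcore[sol_idx] <- dcore[sol_idx] +
      D_sol * (y_in[sol_idx] - y[sol_idx])
    dcore[part_idx] <- dcore[part_idx] +
      (if (batch) 0 else Q / V_liq) * y_in[part_idx] - theta_x * y[part_idx]

    dy <- numeric(n)
    dy[1:24] <- dcore
    dy[idx[["S_cat"]]] <- D_sol * (y_in[["S_cat"]] - y[idx[["S_cat"]]])
    dy[idx[["S_an"]]] <- D_sol * (y_in[["S_an"]] - y[idx[["S_an"]]])

    if (formulation == "ode") {
      rho_AB <- ion_equilibria(st, S_H, p, mode = "ode")
      dy[idx[.ion_names]] <- -rho_AB
    }

    gf <- gas_flow(st, p)
    q <- gf$q_gas
    pp <- gf$partial_pressures
    dy[idx[["S_gas_h2"]]] <- -y[idx[["S_gas_h2"]]] * q / V_gas +
      rhoT[["rhoT_h2"]] * V_liq / V_gas
    dy[idx[["S_gas_ch4"]]] <- -y[idx[["S_gas_ch4"]]] * q / V_gas +
      rhoT[["rhoT_ch4"]] * V_liq / V_gas
    dy[idx[["S_gas_co2"]]] <- -y[idx[["S_gas_co2"]]] * q / V_gas +
      rhoT[["rhoT_co2"]] * V_liq / V_gas
    dy[idx[["S_gas_n2"]]] <- -y[idx[["S_gas_n2"]]] * q / V_gas

    ## methane accounting (per m3 of liquid, kg COD)
    dy[idx[["cum_ch4_cod"]]] <- rhoT[["rhoT_ch4"]]
    dy[idx[["cum_ch4_gas_cod"]]] <- q * pp[["p_ch4"]] /
      (p$R * p$T_op) * 64 / V_liq

    list(dy, pH = pH, q_gas = q, p_ch4 = pp[["p_ch4"]],
         p_co2 = pp[["p_co2"]])
  }
}

#' Evaluate the system right-hand side at a state
#'
#' Convenience wrapper evaluating the derivative vector once, mainly for
#' steady-state residual checks.
#'
#' @inheritParams make_adm1_rhs
#' @param state an `adm1_state` (full layout); components not carried by the
#'   chosen formulation are ignored.
#' @param t time (d), irrelevant for this autonomous system.
#' @return named list with `derivatives` (named vector) and auxiliaries.
#' @export
system_rhs <- function(state, influent, config, p,
                       formulation = c("dae", "ode"), t = 0) {
  formulation <- match.arg(formulation)
  f <- make_adm1_rhs(influent, config, p, formulation)
  nms <- if (formulation == "dae") .dae_state_names() else .ode_state_names()
  y <- unclass(state)[nms]
  out <- f(t, y, NULL)
  list(derivatives = stats::setNames(out[[1]], nms),
       pH = out$pH, q_gas = out$q_gas)
}
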