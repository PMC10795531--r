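## Inlined right-hand side used by default for integration.
##
## Numerically identical to the modular path assembled from
## process_rates(), gas_transfer(), gas_flow(), solve_hydrogen_ion() and
## ion_equilibria() (asserted by tests on random states); written with
## scalar indexing and a local Newton pH solve to keep stiff integration
## inside interactive runtimes.

.make_fast_rhs <- function(influent, config, p, formulation) {
  nu_t <- t(petersen_matrix(p))      # 24 x 19
  y_in <- unclass(influent)[c(.core_names, "S_cat", "S_an")]
  batch <- config$mode == "batch"
  V_liq <- config$V_liq; V_gas <- config$V_gas
  Q <- if (batch) 0 else config$Q
  vols <- effective_volumes(V_liq, config$chi, config$kappa)
  D_sol <- if (batch) 0 else Q / vols$V_s
  D_part_in <- if (batch) 0 else Q / V_liq
  theta_x <- if (batch) 0 else 1 / (config$tresX + vols$V_p / Q)
  inhib_on <- isTRUE(config$inhibition_enabled)
  ode <- formulation == "ode"
  n <- if (ode) 38L else 32L
  i_gas <- if (ode) 33L else 27L   # first gas index
  RT <- p$R * p$T_op

  ## hoist parameters
  k_dis <- p$k_dis; k_hch <- p$k_hyd_ch; k_hpr <- p$k_hyd_pr
  k_hli <- p$k_hyd_li
  km_su <- p$k_m_su; KS_su <- p$K_S_su; km_aa <- p$k_m_aa; KS_aa <- p$K_S_aa
  km_fa <- p$k_m_fa; KS_fa <- p$K_S_fa; km_c4 <- p$k_m_c4; KS_c4 <- p$K_S_c4
  km_pro <- p$k_m_pro; KS_pro <- p$K_S_pro; km_ac <- p$k_m_ac
  KS_ac <- p$K_S_ac; km_h2 <- p$k_m_h2; KS_h2 <- p$K_S_h2
  kd <- c(p$k_dec_X_su, p$k_dec_X_aa, p$k_dec_X_fa, p$k_dec_X_c4,
          p$k_dec_X_pro, p$k_dec_X_ac, p$k_dec_X_h2)
  KI_fa <- p$K_I_h2_fa; KI_c4 <- p$K_I_h2_c4; KI_pro <- p$K_I_h2_pro
  KI_nh3 <- p$K_I_nh3; KS_IN <- p$K_S_IN
  UL_aa <- p$pH_UL_aa; LL_aa <- p$pH_LL_aa
  UL_ac <- p$pH_UL_ac; LL_ac <- p$pH_LL_ac
  UL_h2 <- p$pH_UL_h2; LL_h2 <- p$pH_LL_h2
  Ka_va <- p$K_a_va; Ka_bu <- p$K_a_bu; Ka_pro <- p$K_a_pro
  Ka_ac <- p$K_a_ac; Ka_co2 <- p$K_a_co2; Ka_IN <- p$K_a_IN
  Kw <- p$K_h2o
  kLa <- p$k_L_a; KH_h2 <- p$K_H_h2; KH_ch4 <- p$K_H_ch4
  KH_co2 <- p$K_H_co2
  kp <- p$k_p; P_atm <- p$P_atm; p_h2o <- p$p_gas_h2o
  kab <- c(p$k_AB_va, p$k_AB_bu, p$k_AB_pro, p$k_AB_ac, p$k_AB_co2,
           p$k_AB_IN)

  cache <- new.env(parent = emptyenv())
  cache$S_H <- 1e-7

  solve_pH <- function(S_va, S_bu, S_pro, S_ac, S_IC, S_IN, S_cat, S_an) {
    lo <- 1e-14; hi <- 1
    x <- cache$S_H
    if (x <= lo || x >= hi) x <- 1e-7
    for (it in 1:100) {
      fx <- S_cat + S_IN * x / (Ka_IN + x) + x -
        S_IC * Ka_co2 / (Ka_co2 + x) -
        S_ac * Ka_ac / (Ka_ac + x) / 64 -
        S_pro * Ka_pro / (Ka_pro + x) / 112 -
        S_bu * Ka_bu / (Ka_bu + x) / 160 -
        S_va * Ka_va / (Ka_va + x) / 208 -
        Kw / x - S_an
      if (abs(fx) < 1e-12) break
      if (fx > 0) hi <- x else lo <- x
      gx <- S_IN * Ka_IN / (Ka_IN + x)^2 + 1 +
        S_IC * Ka_co2 / (Ka_co2 + x)^2 +
        S_ac * Ka_ac / (Ka_ac + x)^2 / 64 +
        S_pro * Ka_pro / (Ka_pro + x)^2 / 112 +
        S_bu * Ka_bu / (Ka_bu + x)^2 / 160 +
        S_va * Ka_va / (Ka_va + x)^2 / 208 +
        Kw / x^2
      xn <- x - fx / gx
      if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- sqrt(lo * hi)
      x <- xn
    }
    cache$S_H <- x
    x
  }

  function(t, y, parms) {
    S_su <- max(y[1], 0); S_aa <- max(y[2], 0); S_fa <- max(y[3], 0)
    S_va <- max(y[4], 0); S_bu <- max(y[5], 0); S_pro <- max(y[6], 0)
    S_ac <- max(y[7], 0); S_h2 <- max(y[8], 0); S_ch4 <- max(y[9], 0)
    S_IC <- max(y[10], 0); S_IN <- max(y[11], 0)
    X_c <- max(y[13], 0); X_ch <- max(y[14], 0); X_pr <- max(y[15], 0)
    X_li <- max(y[16], 0)
    Xb <- pmax(y[17:23], 0)          # the seven biomass groups
    S_cat <- y[25]; S_an <- y[26]

    if (ode) {
      sva_i <- max(y[27], 0); sbu_i <- max(y[28], 0)
      spro_i <- max(y[29], 0); sac_i <- max(y[30], 0)
      shco3 <- max(y[31], 0); snh3 <- max(y[32], 0)
      theta <- S_cat + (S_IN - snh3) - shco3 - sac_i / 64 - spro_i / 112 -
        sbu_i / 160 - sva_i / 208 - S_an
      S_H <- -theta / 2 + sqrt(theta * theta + 4 * Kw) / 2
    } else {
      S_H <- solve_pH(S_va, S_bu, S_pro, S_ac, S_IC, S_IN, S_cat, S_an)
      shco3 <- S_IC * Ka_co2 / (Ka_co2 + S_H)
      snh3 <- S_IN * Ka_IN / (Ka_IN + S_H)
    }
    pH <- -log10(S_H)

    if (inhib_on) {
      I_aa <- if (pH >= UL_aa) 1 else
        exp(-3 * ((pH - UL_aa) / (UL_aa - LL_aa))^2)
      I_ac <- if (pH >= UL_ac) 1 else
        exp(-3 * ((pH - UL_ac) / (UL_ac - LL_ac))^2)
      I_h2g <- if (pH >= UL_h2) 1 else
        exp(-3 * ((pH - UL_h2) / (UL_h2 - LL_h2))^2)
      Ih2_fa <- 1 / (1 + S_h2 / KI_fa)
      Ih2_c4 <- 1 / (1 + S_h2 / KI_c4)
      Ih2_pro <- 1 / (1 + S_h2 / KI_pro)
      Inh3 <- 1 / (1 + snh3 / KI_nh3)
    } else {
      I_aa <- I_ac <- I_h2g <- Ih2_fa <- Ih2_c4 <- Ih2_pro <- Inh3 <- 1
    }
    IIN <- S_IN / (S_IN + KS_IN)
    I_ferm <- I_aa * IIN

    c4 <- S_va + S_bu
    r <- c(
      k_dis * X_c, k_hch * X_ch, k_hpr * X_pr, k_hli * X_li,
      km_su * S_su / (KS_su + S_su) * Xb[1] * I_ferm,
      km_aa * S_aa / (KS_aa + S_aa) * Xb[2] * I_ferm,
      km_fa * S_fa / (KS_fa + S_fa) * Xb[3] * I_ferm * Ih2_fa,
      if (c4 > 0) km_c4 * S_va / (KS_c4 + S_va) * Xb[4] * (S_va / c4) *
        I_ferm * Ih2_c4 else 0,
      if (c4 > 0) km_c4 * S_bu / (KS_c4 + S_bu) * Xb[4] * (S_bu / c4) *
        I_ferm * Ih2_c4 else 0,
      km_pro * S_pro / (KS_pro + S_pro) * Xb[5] * I_ferm * Ih2_pro,
      km_ac * S_ac / (KS_ac + S_ac) * Xb[6] * I_ac * IIN * Inh3,
      km_h2 * S_h2 / (KS_h2 + S_h2) * Xb[7] * I_h2g * IIN,
      kd * Xb)
    dy24 <- as.numeric(nu_t %*% r)

    ## gas phase
    p_h2 <- max(y[i_gas], 0) * RT / 16
    p_ch4 <- max(y[i_gas + 1L], 0) * RT / 64
    p_co2 <- max(y[i_gas + 2L], 0) * RT
    p_n2 <- max(y[i_gas + 3L], 0) * RT
    rT_h2 <- kLa * (y[8] - 16 * KH_h2 * p_h2)
    rT_ch4 <- kLa * (y[9] - 64 * KH_ch4 * p_ch4)
    rT_co2 <- kLa * (S_IC - shco3 - KH_co2 * p_co2)
    dy24[8] <- dy24[8] - rT_h2
    dy24[9] <- dy24[9] - rT_ch4
    dy24[10] <- dy24[10] - rT_co2

    dy24[1:12] <- dy24[1:12] + D_sol * (y_in[1:12] - y[1:12])
    dy24[13:24] <- dy24[13:24] + D_part_in * y_in[13:24] -
      theta_x * y[13:24]

    P_gas <- p_h2 + p_ch4 + p_co2 + p_n2 + p_h2o
    q <- kp * (P_gas - P_atm)
    if (q < 0) q <- 0

    dy <- numeric(n)
    dy[1:24] <- dy24
    dy[25] <- D_sol * (y_in[25] - y[25])
    dy[26] <- D_sol * (y_in[26] - y[26])
    if (ode) {
      dy[27] <- -kab[1] * (sva_i * (Ka_va + S_H) - Ka_va * S_va)
      dy[28] <- -kab[2] * (sbu_i * (Ka_bu + S_H) - Ka_bu * S_bu)
      dy[29] <- -kab[3] * (spro_i * (Ka_pro + S_H) - Ka_pro * S_pro)
      dy[30] <- -kab[4] * (sac_i * (Ka_ac + S_H) - Ka_ac * S_ac)
      dy[31] <- -kab[5] * (shco3 * (Ka_co2 + S_H) - Ka_co2 * S_IC)
      dy[32] <- -kab[6] * (snh3 * (Ka_IN + S_H) - Ka_IN * S_IN)
    }
    dy[i_gas] <- -y[i_gas] * q / V_gas + rT_h2 * V_liq / V_gas
    dy[i_gas + 1L] <- -y[i_gas + 1L] * q / V_gas + rT_ch4 * V_liq / V_gas
    dy[i_gas + 2L] <- -y[i_gas + 2L] * q / V_gas + rT_co2 * V_liq / V_gas
    dy[i_gas + 3L] <- -y[i_gas + 3L] * q / V_gas
    dy[i_gas + 4L] <- rT_ch4
    dy[i_gas + 5L] <- q * p_ch4 / RT * 64 / V_liq

    list(dy, pH = pH, q_gas = q, p_ch4 = p_ch4, p_co2 = p_co2)
  }
}
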