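#' Default ADM1/BSM2 model parameters
#'
#' Returns the complete stoichiometric, biochemical and physicochemical
#' parameter set of the BSM2 variant of ADM1 (Rosen & Jeppsson formulation),
#' including the four site-calibrated modifications used throughout this
#' package: `K_I_h2_fa = 5e-4` (BSM2 default `5e-6`), `pH_LL_ac = 5.9`
#' (default `6`), `V_liq = 3485.4` m3 (default `3400`) and
#' `Q_ad = 246.67` m3/d (default `170`).
#'
#' All equilibrium and Henry constants are already evaluated at the operating
#' temperature `T_op = 308.15` K; no van't Hoff correction is applied at run
#' time, so the table is used exactly as configured.
#'
#' Units: first-order and Monod maximum rates in 1/d, half-saturation
#' constants in kg COD/m3 (except `K_S_IN`, M), inhibition constants in
#' kg COD/m3 for hydrogen and M for free ammonia, carbon/nitrogen contents in
#' kmole per kg COD, volumes in m3, flows in m3/d, pressures in bar.
#'
#' @param overrides named list (or named numeric vector) of parameter values
#'   replacing the defaults; unknown names are an error. The default set is
#'   never mutated: a new parameter object is returned.
#' @param calibrated logical; if `FALSE`, the four calibrated entries revert
#'   to their original BSM2 values.
#' @return An object of class `adm1_parameters`: a named list of numeric
#'   scalars.
#' @export
#' @examples
#' p <- adm1_parameters()
#' p$k_dis          # 0.5 1/d
#' p$K_I_h2_fa      # 5e-4 (calibrated)
#' adm1_parameters(list(k_L_a = 100))$k_L_a
adm1_parameters <- function(overrides = NULL, calibrated = TRUE) {
  p <- list(
    ## physicochemical frame
    R = 0.083145,          # bar/(M K)
    T_base = 298.15,       # K
    T_op = 308.15,         # K
    T_ad = 308.15,         # K
    P_atm = 1.013,         # bar

    ## disintegration fractions (COD basis)
    f_sI_xc = 0.1, f_xI_xc = 0.2, f_ch_xc = 0.2, f_pr_xc = 0.2, f_li_xc = 0.3,

    ## nitrogen contents, kmole N / kg COD
    N_xc = 0.002685714, N_I = 0.004286, N_aa = 0.007, N_bac = 0.005714286,

    ## carbon contents, kmole C / kg COD
    C_xc = 0.02786, C_sI = 0.03, C_ch = 0.0313, C_pr = 0.03, C_li = 0.022,
    C_xI = 0.03, C_su = 0.0313, C_aa = 0.03, C_fa = 0.0217, C_va = 0.024,
    C_bu = 0.025, C_pro = 0.0268, C_ac = 0.0313, C_bac = 0.0313,
    C_ch4 = 0.0156,

    ## catabolic product fractions
    f_fa_li = 0.95,
    f_h2_su = 0.19, f_bu_su = 0.13, f_pro_su = 0.27, f_ac_su = 0.41,
    f_h2_aa = 0.06, f_va_aa = 0.23, f_bu_aa = 0.26, f_pro_aa = 0.05,
    f_ac_aa = 0.4,
    ## fixed ADM1 product splits for LCFA, valerate, butyrate, propionate
    f_ac_fa = 0.7, f_h2_fa = 0.3,
    f_pro_va = 0.54, f_ac_va = 0.31, f_h2_va = 0.15,
    f_ac_bu = 0.8, f_h2_bu = 0.2,
    f_ac_pro = 0.57, f_h2_pro = 0.43,

    ## yields (kg COD biomass / kg COD substrate)
    Y_su = 0.1, Y_aa = 0.08, Y_fa = 0.06, Y_c4 = 0.06, Y_pro = 0.04,
    Y_ac = 0.05, Y_h2 = 0.06,

    ## first-order extracellular kinetics, 1/d
    k_dis = 0.5, k_hyd_ch = 10, k_hyd_pr = 10, k_hyd_li = 10,

    ## uptake kinetics
    K_S_IN = 1e-4,                               # M
    k_m_su = 30, K_S_su = 0.5,
    k_m_aa = 50, K_S_aa = 0.3,
    k_m_fa = 6, K_S_fa = 0.4, K_I_h2_fa = 5e-4,  # calibrated (5e-6)
    k_m_c4 = 20, K_S_c4 = 0.2, K_I_h2_c4 = 1e-5,
    k_m_pro = 13, K_S_pro = 0.1, K_I_h2_pro = 3.5e-6,
    k_m_ac = 8, K_S_ac = 0.15, K_I_nh3 = 0.0018, # M
    k_m_h2 = 35, K_S_h2 = 7e-6,

    ## pH inhibition limits
    pH_UL_aa = 5.5, pH_LL_aa = 4,
    pH_UL_ac = 7, pH_LL_ac = 5.9,                # calibrated (6)
    pH_UL_h2 = 6, pH_LL_h2 = 5,

    ## biomass decay, 1/d
    k_dec_X_su = 0.02, k_dec_X_aa = 0.02, k_dec_X_fa = 0.02,
    k_dec_X_c4 = 0.02, k_dec_X_pro = 0.02, k_dec_X_ac = 0.02,
    k_dec_X_h2 = 0.02,

    ## acid-base equilibria at T_op, M
    K_h2o = 2.08e-14,
    K_a_va = 1.38e-5, K_a_bu = 1.51e-5, K_a_pro = 1.32e-5, K_a_ac = 1.74e-5,
    K_a_co2 = 4.94e-7, K_a_IN = 1.11e-9,
    ## kinetic acid-base rates for the ODE formulation, 1/(M d)
    k_AB_va = 1e10, k_AB_bu = 1e10, k_AB_pro = 1e10, k_AB_ac = 1e10,
    k_AB_co2 = 1e10, k_AB_IN = 1e10,

    ## gas phase
    p_gas_h2o = 0.055667745,  # bar at T_op
    k_p = 50000,              # m3/(d bar)
    k_L_a = 200,              # 1/d
    K_H_co2 = 0.027146693,    # M/bar at T_op
    K_H_ch4 = 0.001161903,
    K_H_h2 = 0.000738465,

    ## reactor geometry and flow (calibrated V_liq, Q_ad)
    V_liq = 3485.4, V_gas = 300, Q_ad = 246.67, tresX = 40
  )
  if (!calibrated) {
    p$K_I_h2_fa <- 5e-6
    p$pH_LL_ac <- 6
    p$V_liq <- 3400
    p$Q_ad <- 170
  }
  if (!is.null(overrides)) {
    overrides <- as.list(overrides)
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("parameter '", nm, "' must be a finite numeric scalar",
             call. = FALSE)
      p[[nm]] <- as.numeric(v)
    }
  }
  class(p) <- "adm1_parameters"
  validate_parameters(p)
  p
}

#' Validate an ADM1 parameter set
#'
#' Checks structural invariants: unit closure of the disintegration and
#' fermentation product fractions, exact carbon closure of disintegration,
#' nitrogen closure to 4 significant figures, positivity of rate and
#' equilibrium constants, and ordering of the pH inhibition limits.
#'
#' @param p an `adm1_parameters` object.
#' @return `p` invisibly; stops with an informative message on violation.
#' @export
validate_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (any(!num))
    stop("non-numeric parameter entry: ", paste(names(p)[!num], collapse = ", "),
         call. = FALSE)
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  tol <- 1e-10
  chk(abs(p$f_sI_xc + p$f_xI_xc + p$f_ch_xc + p$f_pr_xc + p$f_li_xc - 1) < tol,
      "disintegration fractions must sum to 1")
  chk(abs(p$f_h2_su + p$f_bu_su + p$f_pro_su + p$f_ac_su - 1) < tol,
      "sugar fermentation fractions must sum to 1")
  chk(abs(p$f_h2_aa + p$f_va_aa + p$f_bu_aa + p$f_pro_aa + p$f_ac_aa - 1) < tol,
      "amino-acid fermentation fractions must sum to 1")
  c_close <- p$f_sI_xc * p$C_sI + p$f_ch_xc * p$C_ch + p$f_pr_xc * p$C_pr +
    p$f_li_xc * p$C_li + p$f_xI_xc * p$C_xI
  chk(abs(c_close - p$C_xc) < 1e-8,
      "carbon content of composites must close the disintegration balance")
  n_close <- p$f_sI_xc * p$N_I + p$f_pr_xc * p$N_aa + p$f_xI_xc * p$N_I
  chk(abs(n_close - p$N_xc) / p$N_xc < 5e-4,
      "nitrogen content of composites must close the disintegration balance")
  pos <- c("k_dis", "k_hyd_ch", "k_hyd_pr", "k_hyd_li", "k_m_su", "k_m_aa",
           "k_m_fa", "k_m_c4", "k_m_pro", "k_m_ac", "k_m_h2", "K_S_su",
           "K_S_aa", "K_S_fa", "K_S_c4", "K_S_pro", "K_S_ac", "K_S_h2",
           "K_S_IN", "K_I_h2_fa", "K_I_h2_c4", "K_I_h2_pro", "K_I_nh3",
           "K_h2o", "K_a_va", "K_a_bu", "K_a_pro", "K_a_ac", "K_a_co2",
           "K_a_IN", "K_H_co2", "K_H_ch4", "K_H_h2", "k_L_a", "k_p",
           "V_liq", "V_gas")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  chk(length(bad) == 0,
      paste0("parameters must be strictly positive: ",
             paste(bad, collapse = ", ")))
  chk(p$pH_UL_aa > p$pH_LL_aa && p$pH_UL_ac > p$pH_LL_ac &&
        p$pH_UL_h2 > p$pH_LL_h2,
      "each pH_UL must exceed its pH_LL")
  invisible(p)
}

#' @export
print.adm1_parameters <- function(x, ...) {
  cat("ADM1/BSM2 parameter set:", length(x), "constants\n")
  cat("  k_dis =", x$k_dis, "1/d; k_L_a =", x$k_L_a, "1/d; T_op =",
      x$T_op, "K\n")
  cat("  V_liq =", x$V_liq, "m3; V_gas =", x$V_gas, "m3; Q_ad =",
      x$Q_ad, "m3/d\n")
  invisible(x)
}

#' Read / write a parameter table as a two-column CSV
#'
#' The CSV mirrors the model symbol names exactly (`parameter,value`).
#' Reading starts from the packaged defaults and overrides any entry present
#' in the file, so a partial table is valid.
#'
#' @param file path to a CSV file with columns `parameter` and `value`.
#' @param p an `adm1_parameters` object to serialize.
#' @return `read_parameters()` returns an `adm1_parameters` object;
#'   `write_parameters()` returns `file` invisibly.
#' @export
read_parameters <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file, call. = FALSE)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(d)))
    stop("parameter CSV must have columns 'parameter' and 'value'",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(d$value))
  if (anyNA(vals))
    stop("non-numeric parameter value for: ",
         paste(d$parameter[is.na(vals)], collapse = ", "), call. = FALSE)
  adm1_parameters(overrides = stats::setNames(as.list(vals), d$parameter))
}

#' @rdname read_parameters
#' @export
write_parameters <- function(p, file) {
  stopifnot(inherits(p, "adm1_parameters"))
  d <- data.frame(parameter = names(p),
                  value = formatC(vapply(p, identity, numeric(1)),
                                  digits = 17, format = "g"))
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
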