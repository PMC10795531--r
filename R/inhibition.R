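#' Lower-limit pH inhibition function
#'
#' The BSM2 form of the lower-only pH inhibition switch:
#' `exp(-3 * ((pH - pH_UL) / (pH_UL - pH_LL))^2)` for `pH < pH_UL`, and 1
#' otherwise. Continuous in pH, equal to `exp(-3)` at the lower limit.
#'
#' @param pH pH value(s).
#' @param pH_UL upper limit above which there is no inhibition.
#' @param pH_LL lower limit at which the factor is `exp(-3)` (~0.0498).
#' @return inhibition factor(s) in (0, 1].
#' @export
#' @examples
#' ph_inhibition_lower(7, 7, 5.9)     # 1
#' ph_inhibition_lower(5.9, 7, 5.9)   # exp(-3)
ph_inhibition_lower <- function(pH, pH_UL, pH_LL) {
  if (pH_UL <= pH_LL)
    stop("pH_UL must exceed pH_LL", call. = FALSE)
  ifelse(pH >= pH_UL, 1,
         exp(-3 * ((pH - pH_UL) / (pH_UL - pH_LL))^2))
}

#' Non-pH inhibition and limitation factors
#'
#' Non-competitive inhibition by dissolved hydrogen
#' (`1 / (1 + S_h2 / K_I)`) on the LCFA, C4 and propionate oxidizers,
#' non-competitive free-ammonia inhibition of acetoclastic methanogenesis,
#' and the inorganic-nitrogen growth limitation `S_IN / (S_IN + K_S_IN)`
#' shared by all uptake processes.
#'
#' @param S_h2 dissolved hydrogen, kg COD/m3.
#' @param S_nh3 free ammonia, M.
#' @param S_IN total inorganic nitrogen, M.
#' @param p an `adm1_parameters` object.
#' @return named list with `I_h2_fa`, `I_h2_c4`, `I_h2_pro`, `I_nh3`,
#'   `I_IN_lim`, each in (0, 1].
#' @export
secondary_inhibitions <- function(S_h2, S_nh3, S_IN, p) {
  if (S_h2 < 0 || S_nh3 < 0 || S_IN < 0)
    stop("inhibitor concentrations must be non-negative", call. = FALSE)
  list(I_h2_fa  = 1 / (1 + S_h2 / p$K_I_h2_fa),
       I_h2_c4  = 1 / (1 + S_h2 / p$K_I_h2_c4),
       I_h2_pro = 1 / (1 + S_h2 / p$K_I_h2_pro),
       I_nh3    = 1 / (1 + S_nh3 / p$K_I_nh3),
       I_IN_lim = S_IN / (S_IN + p$K_S_IN))
}

#' All inhibition factors at a given state
#'
#' Combines the three group-specific pH switches with the secondary factors.
#' When `enabled = FALSE` (the batch BMP convention, where temperature and pH
#' are controlled), every factor except the inorganic-nitrogen limitation is
#' forced to 1.
#'
#' @param pH liquid pH.
#' @param S_h2 dissolved hydrogen, kg COD/m3.
#' @param S_nh3 free ammonia, M.
#' @param S_IN inorganic nitrogen, M.
#' @param p an `adm1_parameters` object.
#' @param enabled logical master switch for the pH/H2/NH3 factors.
#' @return named list of the eight factors, all in (0, 1].
#' @export
inhibition_factors <- function(pH, S_h2, S_nh3, S_IN, p, enabled = TRUE) {
  sec <- secondary_inhibitions(S_h2, S_nh3, S_IN, p)
  if (enabled) {
    out <- list(
      I_pH_aa = ph_inhibition_lower(pH, p$pH_UL_aa, p$pH_LL_aa),
      I_pH_ac = ph_inhibition_lower(pH, p$pH_UL_ac, p$pH_LL_ac),
      I_pH_h2 = ph_inhibition_lower(pH, p$pH_UL_h2, p$pH_LL_h2),
      I_h2_fa = sec$I_h2_fa, I_h2_c4 = sec$I_h2_c4,
      I_h2_pro = sec$I_h2_pro, I_nh3 = sec$I_nh3)
  } else {
    out <- list(I_pH_aa = 1, I_pH_ac = 1, I_pH_h2 = 1,
                I_h2_fa = 1, I_h2_c4 = 1, I_h2_pro = 1, I_nh3 = 1)
  }
  out$I_IN_lim <- sec$I_IN_lim
  out
}
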