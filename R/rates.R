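#' Biochemical process rates
#'
#' Evaluates the 19 process rates of the BSM2 ADM1 at a state: first-order
#' disintegration and hydrolysis, Monod substrate uptake with the wired
#' inhibition products, and first-order biomass decay. The valerate and
#' butyrate uptakes share the C4-degrading biomass and compete through the
#' factors `S_va/(S_va+S_bu)` and `S_bu/(S_va+S_bu)`.
#'
#' Inhibition wiring: the acidogenic/acetogenic pH switch and the
#' inorganic-nitrogen limitation multiply all acidogenic and acetogenic
#' uptakes; hydrogen inhibition additionally multiplies the LCFA, C4 and
#' propionate uptakes; acetate uptake carries the acetate-group pH switch,
#' nitrogen limitation and free-ammonia inhibition; hydrogen uptake carries
#' the hydrogen-group pH switch and nitrogen limitation.
#'
#' @param state an `adm1_state` (or named vector with the core components).
#' @param inhibition list of factors as returned by [inhibition_factors()].
#' @param p an `adm1_parameters` object.
#' @return named numeric vector of 19 rates, kg COD/m3/d, all finite and
#'   non-negative for a non-negative state.
#' @export
#' @examples
#' p <- adm1_parameters()
#' s <- adm1_state(X_c = 40.769)
#' I <- inhibition_factors(7, 0, 0, 1, p)
#' process_rates(s, I, p)[["disintegration"]]  # 20.3845
process_rates <- function(state, inhibition, p) {
  y <- unclass(state)
  if (anyNA(y))
    stop("NaN/NA in state component(s): ",
         paste(names(y)[is.na(y)], collapse = ", "), call. = FALSE)
  ## negative excursions below solver tolerance are treated as zero substrate
  g <- function(nm) max(y[[nm]], 0)
  monod <- function(S, K) S / (K + S)
  I <- inhibition
  I_ferm <- I$I_pH_aa * I$I_IN_lim
  S_va <- g("S_va"); S_bu <- g("S_bu")
  c4_tot <- S_va + S_bu
  r <- c(
    disintegration = p$k_dis * g("X_c"),
    hydrolysis_ch = p$k_hyd_ch * g("X_ch"),
    hydrolysis_pr = p$k_hyd_pr * g("X_pr"),
    hydrolysis_li = p$k_hyd_li * g("X_li"),
    uptake_su = p$k_m_su * monod(g("S_su"), p$K_S_su) * g("X_su") * I_ferm,
    uptake_aa = p$k_m_aa * monod(g("S_aa"), p$K_S_aa) * g("X_aa") * I_ferm,
    uptake_fa = p$k_m_fa * monod(g("S_fa"), p$K_S_fa) * g("X_fa") *
      I_ferm * I$I_h2_fa,
    uptake_va = if (c4_tot > 0)
      p$k_m_c4 * monod(S_va, p$K_S_c4) * g("X_c4") * (S_va / c4_tot) *
        I_ferm * I$I_h2_c4 else 0,
    uptake_bu = if (c4_tot > 0)
      p$k_m_c4 * monod(S_bu, p$K_S_c4) * g("X_c4") * (S_bu / c4_tot) *
        I_ferm * I$I_h2_c4 else 0,
    uptake_pro = p$k_m_pro * monod(g("S_pro"), p$K_S_pro) * g("X_pro") *
      I_ferm * I$I_h2_pro,
    uptake_ac = p$k_m_ac * monod(g("S_ac"), p$K_S_ac) * g("X_ac") *
      I$I_pH_ac * I$I_IN_lim * I$I_nh3,
    uptake_h2 = p$k_m_h2 * monod(g("S_h2"), p$K_S_h2) * g("X_h2") *
      I$I_pH_h2 * I$I_IN_lim,
    decay_X_su = p$k_dec_X_su * g("X_su"),
    decay_X_aa = p$k_dec_X_aa * g("X_aa"),
    decay_X_fa = p$k_dec_X_fa * g("X_fa"),
    decay_X_c4 = p$k_dec_X_c4 * g("X_c4"),
    decay_X_pro = p$k_dec_X_pro * g("X_pro"),
    decay_X_ac = p$k_dec_X_ac * g("X_ac"),
    decay_X_h2 = p$k_dec_X_h2 * g("X_h2"))
  if (any(!is.finite(r)))
    stop("non-finite process rate: ",
         paste(names(r)[!is.finite(r)], collapse = ", "), call. = FALSE)
  r
}
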