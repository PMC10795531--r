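#' Petersen matrix of the 19 biochemical processes
#'
#' Builds the process-by-component stoichiometric coefficient table of the
#' BSM2 ADM1: disintegration, three hydrolyses, eight substrate uptakes and
#' seven biomass decays against the 24 core liquid components. The inorganic
#' carbon column closes the carbon balance of every process
#' (`nu_IC,j = -sum_i C_i nu_ij`) and the inorganic nitrogen column closes
#' the nitrogen balance (`nu_IN,j = -sum_i N_i nu_ij`), so elemental
#' conservation holds exactly by construction for any valid parameter set.
#'
#' @param p an `adm1_parameters` object.
#' @return a 19 x 24 numeric matrix; rows named by process, columns by
#'   component.
#' @export
#' @examples
#' nu <- petersen_matrix(adm1_parameters())
#' nu["disintegration", c("X_c", "X_ch", "S_I")]
petersen_matrix <- function(p) {
  stopifnot(inherits(p, "adm1_parameters"))
  comps <- .core_names
  procs <- c("disintegration", "hydrolysis_ch", "hydrolysis_pr",
             "hydrolysis_li", "uptake_su", "uptake_aa", "uptake_fa",
             "uptake_va", "uptake_bu", "uptake_pro", "uptake_ac",
             "uptake_h2", "decay_X_su", "decay_X_aa", "decay_X_fa",
             "decay_X_c4", "decay_X_pro", "decay_X_ac", "decay_X_h2")
  nu <- matrix(0, nrow = length(procs), ncol = length(comps),
               dimnames = list(procs, comps))
  set <- function(proc, ...) {
    v <- c(...)
    nu[proc, names(v)] <<- v
  }
  set("disintegration", X_c = -1, X_ch = p$f_ch_xc, X_pr = p$f_pr_xc,
      X_li = p$f_li_xc, X_I = p$f_xI_xc, S_I = p$f_sI_xc)
  set("hydrolysis_ch", X_ch = -1, S_su = 1)
  set("hydrolysis_pr", X_pr = -1, S_aa = 1)
  set("hydrolysis_li", X_li = -1, S_fa = p$f_fa_li, S_su = 1 - p$f_fa_li)
  set("uptake_su", S_su = -1,
      S_bu = (1 - p$Y_su) * p$f_bu_su, S_pro = (1 - p$Y_su) * p$f_pro_su,
      S_ac = (1 - p$Y_su) * p$f_ac_su, S_h2 = (1 - p$Y_su) * p$f_h2_su,
      X_su = p$Y_su)
  set("uptake_aa", S_aa = -1,
      S_va = (1 - p$Y_aa) * p$f_va_aa, S_bu = (1 - p$Y_aa) * p$f_bu_aa,
      S_pro = (1 - p$Y_aa) * p$f_pro_aa, S_ac = (1 - p$Y_aa) * p$f_ac_aa,
      S_h2 = (1 - p$Y_aa) * p$f_h2_aa, X_aa = p$Y_aa)
  set("uptake_fa", S_fa = -1,
      S_ac = (1 - p$Y_fa) * p$f_ac_fa, S_h2 = (1 - p$Y_fa) * p$f_h2_fa,
      X_fa = p$Y_fa)
  set("uptake_va", S_va = -1,
      S_pro = (1 - p$Y_c4) * p$f_pro_va, S_ac = (1 - p$Y_c4) * p$f_ac_va,
      S_h2 = (1 - p$Y_c4) * p$f_h2_va, X_c4 = p$Y_c4)
  set("uptake_bu", S_bu = -1,
      S_ac = (1 - p$Y_c4) * p$f_ac_bu, S_h2 = (1 - p$Y_c4) * p$f_h2_bu,
      X_c4 = p$Y_c4)
  set("uptake_pro", S_pro = -1,
      S_ac = (1 - p$Y_pro) * p$f_ac_pro, S_h2 = (1 - p$Y_pro) * p$f_h2_pro,
      X_pro = p$Y_pro)
  set("uptake_ac", S_ac = -1, S_ch4 = 1 - p$Y_ac, X_ac = p$Y_ac)
  set("uptake_h2", S_h2 = -1, S_ch4 = 1 - p$Y_h2, X_h2 = p$Y_h2)
  for (b in c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")) {
    nu[paste0("decay_", b), b] <- -1
    nu[paste0("decay_", b), "X_c"] <- 1
  }

  ## elemental closure
  cc <- carbon_content(p)
  nn <- nitrogen_content(p)
  nu[, "S_IC"] <- -as.vector(nu[, comps != "S_IC"] %*% cc[comps != "S_IC"])
  nu[, "S_IN"] <- -as.vector(nu[, comps != "S_IN"] %*% nn[comps != "S_IN"])
  nu
}

#' Elemental content vectors over the 24 core components
#'
#' Carbon content in kmole C per kg COD (1 for `S_IC` itself) and nitrogen
#' content in kmole N per kg COD (1 for `S_IN`), used for the closure columns
#' of the Petersen matrix and for run-level carbon/nitrogen audits.
#'
#' @param p an `adm1_parameters` object.
#' @return named numeric vector over the core components.
#' @export
carbon_content <- function(p) {
  stats::setNames(c(p$C_su, p$C_aa, p$C_fa, p$C_va, p$C_bu, p$C_pro, p$C_ac,
                    0, p$C_ch4, 1, 0, p$C_sI,
                    p$C_xc, p$C_ch, p$C_pr, p$C_li,
                    rep(p$C_bac, 7), p$C_xI),
                  .core_names)
}

#' @rdname carbon_content
#' @export
nitrogen_content <- function(p) {
  n <- stats::setNames(numeric(length(.core_names)), .core_names)
  n["S_aa"] <- p$N_aa
  n["X_pr"] <- p$N_aa
  n["S_IN"] <- 1
  n["S_I"] <- p$N_I
  n["X_I"] <- p$N_I
  n["X_c"] <- p$N_xc
  n[c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")] <- p$N_bac
  n
}
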