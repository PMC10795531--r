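## State layout -------------------------------------------------------------
## The 24 "core" liquid components follow the conventional ADM1 ordering
## (solubles first, then particulates), then the two strong-ion pools, the
## six weak acid/base ion states, the three headspace gas concentrations, an
## inert headspace gas pool (nitrogen flush of a batch assay) and two
## cumulative methane accounting states.

.core_names <- c("S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac",
                 "S_h2", "S_ch4", "S_IC", "S_IN", "S_I",
                 "X_c", "X_ch", "X_pr", "X_li", "X_su", "X_aa", "X_fa",
                 "X_c4", "X_pro", "X_ac", "X_h2", "X_I")
.ion_names <- c("S_va_ion", "S_bu_ion", "S_pro_ion", "S_ac_ion",
                "S_hco3_ion", "S_nh3")
.gas_names <- c("S_gas_h2", "S_gas_ch4", "S_gas_co2")
.extra_names <- c("S_gas_n2", "cum_ch4_cod", "cum_ch4_gas_cod")

#' State variable names of the ADM1 system
#'
#' @param which one of `"core"` (24 liquid components), `"ions"` (6 weak
#'   acid/base ion states), `"gas"` (3 headspace concentrations) or `"all"`.
#' @return character vector of state names.
#' @export
adm1_state_names <- function(which = c("all", "core", "ions", "gas")) {
  which <- match.arg(which)
  switch(which,
         core = .core_names,
         ions = .ion_names,
         gas = .gas_names,
         all = c(.core_names, "S_cat", "S_an", .ion_names, .gas_names,
                 .extra_names))
}

#' Construct an ADM1 state vector
#'
#' An ADM1 state holds the 24 core liquid components (kg COD/m3; `S_IC` in
#' kmole C/m3, `S_IN` in kmole N/m3), the strong cation/anion pools
#' (kmole/m3), the six weak acid/base ion states, the three headspace gas
#' concentrations (kg COD/m3 for H2/CH4, kmole C/m3 for CO2), an inert
#' headspace pool and two cumulative methane accounting states. Components
#' not supplied default to zero.
#'
#' @param ... named numeric scalars, or a single named vector/list.
#' @return named numeric vector of class `adm1_state`.
#' @export
#' @examples
#' s <- adm1_state(S_su = 0.01, X_c = 40.769)
#' s["X_c"]
adm1_state <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1]]) || is.numeric(args[[1]])))
    args <- as.list(args[[1]])
  full <- stats::setNames(numeric(length(adm1_state_names())),
                          adm1_state_names())
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("state components must be named", call. = FALSE)
    unknown <- setdiff(names(args), names(full))
    if (length(unknown))
      stop("unknown state component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    full[names(args)] <- vapply(args, as.numeric, numeric(1))
  }
  if (anyNA(full)) stop("state contains NA", call. = FALSE)
  structure(full, class = c("adm1_state", "numeric"))
}

#' @export
print.adm1_state <- function(x, ...) {
  cat("ADM1 state (kg COD/m3; IC, IN, ions in kmole/m3):\n")
  core <- unclass(x)[.core_names]
  print(signif(core, 5))
  cat("pH-relevant pools: S_cat =", signif(x[["S_cat"]], 4),
      " S_an =", signif(x[["S_an"]], 4), "\n")
  invisible(x)
}

#' Influent sludge composition of the anaerobic reactor
#'
#' The packaged default influent state: a sewage-sludge feed dominated by
#' complex composites (X_c = 40.769 kg COD/m3) with additional protein
#' (8.127), traces of lipid (0.252) and inert particulate (0.087), the
#' starred entries having been determined by influent calibration against
#' BMP data. Soluble fractions are small seed values.
#'
#' @return an `adm1_state` vector.
#' @export
adm1_influent <- function() {
  adm1_state(
    S_su = 0.01, S_aa = 0.001, S_fa = 0.001, S_va = 0.001, S_bu = 0.001,
    S_pro = 0.001, S_ac = 0.001, S_h2 = 1e-8, S_ch4 = 1e-5,
    S_IC = 0.04, S_IN = 0.01, S_I = 0.02,
    X_c = 40.769, X_ch = 0, X_pr = 8.127, X_li = 0.252,
    X_su = 0, X_aa = 0.01, X_fa = 0.01, X_c4 = 0.01, X_pro = 0.01,
    X_ac = 0.01, X_h2 = 0.01, X_I = 0.087,
    S_cat = 0.04, S_an = 0.10
  )
}

#' Reference digested-sludge state
#'
#' A digested-sludge composition typical of the anaerobic reactor at steady
#' state, packaged as the default initial condition (inoculum) for reactor
#' start-up. Ion and gas states are initialized consistently at run time.
#'
#' @return an `adm1_state` vector.
#' @export
adm1_digested_sludge <- function() {
  adm1_state(
    S_su = 0.015031, S_aa = 0.0067129, S_fa = 0.12853, S_va = 0.014532,
    S_bu = 0.016795, S_pro = 0.020244, S_ac = 0.042027, S_h2 = 2e-7,
    S_ch4 = 0.045, S_IC = 0.08, S_IN = 0.1245, S_I = 3.7066,
    X_c = 5.0183, X_ch = 0.049515, X_pr = 0.15778, X_li = 0.077605,
    X_su = 0.60868, X_aa = 1.4414, X_fa = 0.49932, X_c4 = 0.52954,
    X_pro = 0.16868, X_ac = 1.0750, X_h2 = 0.45639, X_I = 7.5005,
    S_cat = 0.04, S_an = 0.10
  )
}

#' Read / write an ADM1 state vector as a name/value CSV
#'
#' The CSV has columns `variable,value` using the model symbol names
#' (`S_su` ... `X_I`, `S_cat`, `S_an`, optionally ion/gas states). Missing
#' components default to zero, so the influent table format (24 liquid
#' components plus cations/anions) round-trips unchanged.
#'
#' @param file path to the CSV.
#' @param state an `adm1_state` vector.
#' @param keep_zero logical; if `FALSE` (default) zero components are
#'   omitted on write.
#' @return `read_adm1_state()` returns an `adm1_state`;
#'   `write_adm1_state()` returns `file` invisibly.
#' @export
read_adm1_state <- function(file) {
  if (!file.exists(file)) stop("state file not found: ", file, call. = FALSE)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("variable", "value") %in% names(d)))
    stop("state CSV must have columns 'variable' and 'value'", call. = FALSE)
  vals <- suppressWarnings(as.numeric(d$value))
  if (anyNA(vals))
    stop("non-numeric state value for: ",
         paste(d$variable[is.na(vals)], collapse = ", "), call. = FALSE)
  adm1_state(stats::setNames(vals, d$variable))
}

#' @rdname read_adm1_state
#' @export
write_adm1_state <- function(state, file, keep_zero = FALSE) {
  stopifnot(inherits(state, "adm1_state"))
  v <- unclass(state)
  if (!keep_zero) v <- v[v != 0]
  d <- data.frame(variable = names(v),
                  value = formatC(v, digits = 17, format = "g"))
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Total COD of a state
#'
#' Sums every COD-carrying component (all soluble and particulate organics
#' plus biomass; inorganic carbon, nitrogen and strong ions carry no COD).
#' Dissolved hydrogen and methane are included unless `dissolved_gas` is
#' `FALSE`.
#'
#' @param state an `adm1_state` (or named vector with core components).
#' @param dissolved_gas include S_h2 and S_ch4 (default `TRUE`).
#' @return total COD in kg COD/m3.
#' @export
total_cod <- function(state, dissolved_gas = TRUE) {
  cod_names <- setdiff(.core_names, c("S_IC", "S_IN"))
  if (!dissolved_gas) cod_names <- setdiff(cod_names, c("S_h2", "S_ch4"))
  sum(unclass(state)[cod_names])
}
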