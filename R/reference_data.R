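#' Packaged reference BMP assay data
#'
#' Accessors for the plain-text reference datasets shipped with the package,
#' from an 11-day mesophilic sewage-sludge BMP assay (six replicates,
#' 100 mL working volume, 1.1% TVS, initial tCOD 21,903 mg/L) at a large
#' municipal wastewater treatment plant, together with the matching coupled
#' ADM1 simulation outputs:
#'
#' * `bmp_reference_curve()` — daily mean cumulative methane yield of the
#'   assay and the reference simulated curve, mL CH4/g VS.
#' * `bmp_reference_endpoints()` — per-replicate endpoint volumes (NmL) and
#'   yields.
#' * `bmp_reference_biodegradability()` — per-replicate final pH, final
#'   tCOD and COD removal.
#' * `ar_reference_output()` — the reference digested-sludge composition
#'   (reactor output / BMP seed) as an [adm1_state()].
#'
#' @return data.frames (or an `adm1_state`), see above.
#' @export
bmp_reference_curve <- function() {
  utils::read.csv(system.file("extdata", "bmp_reference_curve.csv",
                              package = "adm1sim"))
}

#' @rdname bmp_reference_curve
#' @export
bmp_reference_endpoints <- function() {
  utils::read.csv(system.file("extdata", "bmp_replicate_endpoints.csv",
                              package = "adm1sim"))
}

#' @rdname bmp_reference_curve
#' @export
bmp_reference_biodegradability <- function() {
  utils::read.csv(system.file("extdata", "bmp_biodegradability.csv",
                              package = "adm1sim"))
}

#' @rdname bmp_reference_curve
#' @export
ar_reference_output <- function() {
  read_adm1_state(system.file("extdata", "ar_output_reference.csv",
                              package = "adm1sim"))
}
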