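#' Assemble a BMP assay dataset
#'
#' Holds replicate cumulative methane curves (NmL) on a common day grid
#' starting at day 0 with zero volume, plus assay metadata. Per-day mean,
#' sample standard deviation and standard error are derived on construction.
#'
#' @param days numeric day grid, starting at 0.
#' @param curves numeric matrix, rows = days, columns = replicates, NmL.
#'   Each replicate must be non-decreasing and start at 0.
#' @param working_volume assay working volume, L.
#' @param tvs_fraction volatile-solids mass fraction (g/mL; 0.011 = 1.1%).
#' @param tcod_initial initial total COD, mg/L.
#' @param temperature assay temperature, deg C.
#' @return a list of class `bmp_dataset`.
#' @export
bmp_dataset <- function(days, curves, working_volume = 0.1,
                        tvs_fraction = 0.011, tcod_initial = 21903,
                        temperature = 37) {
  curves <- as.matrix(curves)
  if (length(days) != nrow(curves))
    stop("length(days) must match nrow(curves)", call. = FALSE)
  if (days[1] != 0 || any(curves[1, ] != 0))
    stop("day grid must start at 0 with zero cumulative volume",
         call. = FALSE)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing",
                                 call. = FALSE)
  mono <- apply(curves, 2, function(x) all(diff(x) >= -1e-9))
  if (any(!mono))
    stop("replicate(s) not non-decreasing: ",
         paste(colnames(curves)[!mono] %||% which(!mono), collapse = ", "),
         call. = FALSE)
  if (working_volume <= 0 || tvs_fraction <= 0)
    stop("working volume and TVS fraction must be positive", call. = FALSE)
  if (is.null(colnames(curves)))
    colnames(curves) <- paste0("R", seq_len(ncol(curves)))
  structure(list(days = days, curves = curves,
                 working_volume = working_volume,
                 tvs_fraction = tvs_fraction,
                 tcod_initial = tcod_initial,
                 temperature = temperature,
                 vs_mass = working_volume * 1000 * tvs_fraction),
            class = "bmp_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bmp_dataset <- function(x, ...) {
  cat(sprintf("BMP dataset: %d replicates x %d days, %.3g g VS in %.3g L\n",
              ncol(x$curves), length(x$days), x$vs_mass, x$working_volume))
  ends <- x$curves[nrow(x$curves), ]
  cat("  endpoint NmL:", paste(signif(ends, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a BMP dataset
#'
#' Per-day replicate mean, sample standard deviation (n - 1 denominator)
#' and standard error, plus the endpoint summary in NmL and per-VS yield.
#'
#' @param dataset a `bmp_dataset` with >= 2 replicates.
#' @return list with `per_day` (data.frame `day`, `mean`, `sd`, `se`) and
#'   `endpoint` (list `mean_nml`, `sd_nml`, `mean_yield`, `sd_yield`, `n`).
#' @export
#' @examples
#' d <- bmp_dataset(c(0, 11), rbind(0, c(124, 143, 137, 142, 140, 130)))
#' bmp_summary(d)$endpoint$mean_nml  # 136
bmp_summary <- function(dataset) {
  stopifnot(inherits(dataset, "bmp_dataset"))
  m <- dataset$curves
  if (ncol(m) < 2) stop("need >= 2 replicates to summarize", call. = FALSE)
  per_day <- data.frame(day = dataset$days,
                        mean = rowMeans(m),
                        sd = apply(m, 1, stats::sd))
  per_day$se <- per_day$sd / sqrt(ncol(m))
  ends <- m[nrow(m), ]
  list(per_day = per_day,
       endpoint = list(mean_nml = mean(ends), sd_nml = stats::sd(ends),
                       mean_yield = mean(ends) / dataset$vs_mass,
                       sd_yield = stats::sd(ends) / dataset$vs_mass,
                       n = ncol(m)))
}

#' Methane yield per gram of volatile solids
#'
#' @param cumulative cumulative methane, NmL.
#' @param vs_mass volatile-solids mass, g (working volume x TVS fraction).
#' @return yield in mL CH4 / g VS.
#' @export
#' @examples
#' yield_per_vs(136, 1.1)  # ~124
yield_per_vs <- function(cumulative, vs_mass) {
  if (vs_mass <= 0) stop("vs_mass must be positive", call. = FALSE)
  cumulative / vs_mass
}

#' COD removal percentage
#'
#' `100 * (tcod_i - tcod_f) / tcod_i`, reported to one decimal. A final COD
#' above the initial (possible under measurement noise) warns rather than
#' errors.
#'
#' @param tcod_i initial total COD, mg/L (> 0).
#' @param tcod_f final total COD, mg/L.
#' @return removal percentage, one decimal.
#' @export
#' @examples
#' cod_removal(21903, 16820)  # 23.2
cod_removal <- function(tcod_i, tcod_f) {
  if (any(tcod_i <= 0)) stop("initial COD must be positive", call. = FALSE)
  if (any(tcod_f < 0) || any(tcod_f > tcod_i))
    warning("final COD outside [0, initial]; check measurements")
  round(100 * (tcod_i - tcod_f) / tcod_i, 1)
}

#' Theoretical methane volume from COD removed
#'
#' The COD equivalence of methane: 0.350 Nm3 CH4 per kg COD converted,
#' i.e. 350 NmL per g.
#'
#' @param cod_removed COD converted, g (>= 0).
#' @return theoretical methane volume, NmL.
#' @export
theoretical_methane <- function(cod_removed) {
  if (any(cod_removed < 0)) stop("cod_removed must be >= 0", call. = FALSE)
  350 * cod_removed
}

#' Generate a synthetic BMP dataset from a known influent
#'
#' Forward-simulates the coupled AR-to-BMP methane curve for a known
#' ("true") influent, samples it on the daily grid, and adds independent
#' Gaussian noise per replicate and day (day 0 stays exactly zero).
#' Per-replicate monotonicity is enforced by cumulative maximum, emulating
#' a volumetric displacement reading that cannot decrease. The generating
#' truth is attached for recovery tests.
#'
#' @param true_influent an `adm1_state` influent.
#' @param ar_config,bmp_config reactor configurations for the forward run.
#' @param p an `adm1_parameters` object.
#' @param noise_sd replicate noise standard deviation, NmL.
#' @param n_replicates number of replicates.
#' @param seed random seed (required).
#' @param working_volume,tvs_fraction assay metadata for the dataset.
#' @param true_curve optional precomputed noise-free daily NmL curve
#'   (day 0 first); skips the forward simulation, e.g. for Monte-Carlo
#'   studies of the noise layer itself.
#' @return a `bmp_dataset` with attributes `truth` (the influent),
#'   `true_curve` (noise-free NmL curve) and `seed`.
#' @export
generate_synthetic_bmp <- function(true_influent, ar_config = reactor_config(),
                                   bmp_config = reactor_config("batch",
                                                               V_liq = 1,
                                                               V_gas = 1.5,
                                                               output_dt = 0.5),
                                   p = adm1_parameters(),
                                   noise_sd = 3, n_replicates = 6, seed,
                                   working_volume = 0.1,
                                   tvs_fraction = 0.011, true_curve = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(true_curve)) {
    sim <- couple_ar_bmp(true_influent, ar_config, bmp_config, p)
    curve <- cumulative_methane(sim$bmp, working_volume = working_volume,
                                tvs_fraction = tvs_fraction)
    days <- 0:floor(max(curve$time))
    idx <- vapply(days, function(d) which.min(abs(curve$time - d)),
                  integer(1))
    true_nml <- curve$nml[idx]
  } else {
    true_nml <- true_curve
    days <- seq_along(true_nml) - 1
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_replicates), function(k) {
    y <- true_nml + stats::rnorm(length(days), 0, noise_sd)
    y[1] <- 0
    cummax(pmax(y, 0))
  }, numeric(length(days)))
  colnames(reps) <- paste0("R", seq_len(n_replicates))
  ds <- bmp_dataset(days, reps, working_volume = working_volume,
                    tvs_fraction = tvs_fraction)
  attr(ds, "truth") <- true_influent
  attr(ds, "true_curve") <- true_nml
  attr(ds, "seed") <- seed
  ds
}

#' Read a BMP replicate-curve CSV
#'
#' Expects the dialect `day,R1,R2,...` with cumulative NmL per replicate.
#'
#' @param file CSV path.
#' @param ... metadata passed to [bmp_dataset()].
#' @return a `bmp_dataset`.
#' @export
read_bmp_csv <- function(file, ...) {
  if (!file.exists(file)) stop("BMP file not found: ", file, call. = FALSE)
  d <- utils::read.csv(file)
  if (names(d)[1] != "day")
    stop("first column of a BMP CSV must be 'day'", call. = FALSE)
  bmp_dataset(d$day, as.matrix(d[-1]), ...)
}
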