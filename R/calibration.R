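#' Per-timepoint standard errors from replicate curves
#'
#' The measurement weight used in the calibration objective: the sample
#' standard deviation (n - 1 denominator) across replicates at each
#' timepoint, divided by `sqrt(n)`.
#'
#' @param replicate_curves numeric matrix, rows = timepoints, columns =
#'   replicates (>= 2).
#' @param floor minimum admissible standard error; timepoints below it are
#'   an error unless a positive floor is supplied (degenerate identical
#'   replicates carry no weight information).
#' @return numeric vector of standard errors, one per timepoint.
#' @export
#' @examples
#' standard_errors(matrix(c(124, 143, 137, 142, 140, 130), nrow = 1))
#' # 7.51/sqrt(6) = 3.07
standard_errors <- function(replicate_curves, floor = 0) {
  m <- as.matrix(replicate_curves)
  if (ncol(m) < 2)
    stop("need >= 2 replicates to estimate standard errors; ",
         "supply sigma directly for single-replicate data", call. = FALSE)
  se <- apply(m, 1, stats::sd) / sqrt(ncol(m))
  se <- pmax(se, floor)
  if (any(se <= 0))
    stop("zero standard error at timepoint(s) ",
         paste(which(se <= 0), collapse = ", "),
         "; set a positive `floor`", call. = FALSE)
  se
}

#' Define an influent-calibration problem
#'
#' The inverse problem of the coupled simulator: recover influent sludge
#' composition (and optionally flow) from a measured cumulative methane
#' curve and the measured reactor-output total COD. Free parameters are any
#' of the influent components plus `Q`; the forward model runs the AR to
#' (near) steady state, seeds the batch BMP assay, and samples the yield
#' curve at the observation days.
#'
#' @param free_names character; parameter names among the influent state
#'   components (e.g. `"X_c"`, `"X_pr"`, `"X_li"`, `"X_I"`) plus `"Q"`.
#' @param lower,upper numeric bounds, same length/order as `free_names`.
#' @param obs_days integer days of the observed curve (> 0).
#' @param obs_yield observed cumulative methane at `obs_days`, mL/g VS.
#' @param obs_se per-day standard errors (same length); see
#'   [standard_errors()].
#' @param tcod_meas measured total COD of the reactor output, kg COD/m3, or
#'   `NA` to disable the COD term.
#' @param tcod_weight weight (sigma-equivalent) of the COD residual.
#' @param base_influent influent whose non-free components stay fixed.
#' @param ar_config,bmp_config reactor configurations for the forward model.
#' @param p an `adm1_parameters` object.
#' @param vs_mass,working_volume assay normalization, g and L.
#' @param weighting `"printed"` uses `sum(r^2 / sigma)` (the form printed in
#'   the source formulation); `"classical"` uses `sum(r^2 / sigma^2)`.
#' @param settings DE settings list; see [de_rand_1_bin()].
#' @param restarts number of independent optimizer restarts.
#' @return a list of class `calibration_problem`.
#' @export
calibration_problem <- function(free_names, lower, upper,
                                obs_days, obs_yield, obs_se,
                                tcod_meas = NA_real_, tcod_weight = NULL,
                                base_influent = adm1_influent(),
                                ar_config = reactor_config(duration = 90),
                                bmp_config = reactor_config("batch",
                                                            V_liq = 1,
                                                            V_gas = 1.5,
                                                            output_dt = 0.5),
                                p = adm1_parameters(),
                                vs_mass = 1.1, working_volume = 0.1,
                                weighting = c("printed", "classical"),
                                settings = list(), restarts = 1) {
  weighting <- match.arg(weighting)
  ok_names <- c(.core_names, "S_cat", "S_an", "Q")
  if (!all(free_names %in% ok_names))
    stop("free parameters must be influent components or 'Q'", call. = FALSE)
  if (length(lower) != length(free_names) ||
      length(upper) != length(free_names) || any(lower >= upper))
    stop("bounds must satisfy lower < upper for every free parameter",
         call. = FALSE)
  if (length(obs_days) != length(obs_yield) ||
      length(obs_se) != length(obs_yield))
    stop("obs_days, obs_yield and obs_se must have equal length",
         call. = FALSE)
  if (any(obs_se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  n_obs <- length(obs_yield) + !is.na(tcod_meas)
  if (n_obs < length(free_names))
    stop("need at least as many observations as free parameters",
         call. = FALSE)
  if (is.na(tcod_meas)) tcod_weight <- NULL
  else if (is.null(tcod_weight)) tcod_weight <- stats::median(obs_se)
  structure(list(free_names = free_names, lower = lower, upper = upper,
                 obs_days = obs_days, obs_yield = obs_yield, obs_se = obs_se,
                 tcod_meas = tcod_meas, tcod_weight = tcod_weight,
                 base_influent = base_influent, ar_config = ar_config,
                 bmp_config = bmp_config, p = p, vs_mass = vs_mass,
                 working_volume = working_volume, weighting = weighting,
                 settings = settings, restarts = restarts),
            class = "calibration_problem")
}

## Forward model: curve at obs_days (mL/g VS) and AR-output total COD.
forward_model <- function(Pi, problem) {
  pr <- problem
  infl <- pr$base_influent
  cfg <- pr$ar_config
  for (i in seq_along(pr$free_names)) {
    nm <- pr$free_names[i]
    if (nm == "Q") {
      cfg <- reactor_config(mode = "continuous", V_liq = cfg$V_liq,
                            V_gas = cfg$V_gas, Q = Pi[i], tresX = cfg$tresX,
                            chi = cfg$chi, kappa = cfg$kappa,
                            inhibition_enabled = cfg$inhibition_enabled,
                            duration = cfg$duration,
                            output_dt = cfg$output_dt,
                            formulation = cfg$formulation)
    } else infl[[nm]] <- Pi[i]
  }
  ar <- simulate_ar(infl, cfg, pr$p, require_steady = FALSE)
  bmp <- simulate_bmp(ar$final_state, pr$bmp_config, pr$p)
  curve <- cumulative_methane(bmp, vs_mass = pr$vs_mass,
                              working_volume = pr$working_volume)
  idx <- vapply(pr$obs_days, function(d) which.min(abs(curve$time - d)),
                integer(1))
  list(yield = curve$ml_per_gvs[idx],
       tcod_out = total_cod(ar$final_state, dissolved_gas = FALSE),
       curve = curve, ar = ar, bmp = bmp)
}

#' Calibration residuals at a parameter vector
#'
#' `r_i = observed - simulated` at each observation day, plus (when a
#' measured total COD is configured) the reactor-output COD mismatch as an
#' extra weighted residual. Forward-model failures return a large-penalty
#' sentinel so a population optimizer can continue past pathological
#' parameter vectors.
#'
#' @param Pi numeric parameter vector in the order of
#'   `problem$free_names`.
#' @param problem a `calibration_problem`.
#' @return numeric residual vector with attribute `"sigma"` (the matching
#'   weights); on forward failure, a vector of `1e6` with attribute
#'   `"failed"` carrying the condition message.
#' @export
calibration_residuals <- function(Pi, problem) {
  fw <- tryCatch(forward_model(Pi, problem), error = function(e) e)
  n <- length(problem$obs_yield) + !is.na(problem$tcod_meas)
  if (inherits(fw, "error")) {
    r <- rep(1e6, n)
    attr(r, "sigma") <- c(problem$obs_se,
                          if (!is.na(problem$tcod_meas)) problem$tcod_weight)
    attr(r, "failed") <- conditionMessage(fw)
    return(r)
  }
  r <- problem$obs_yield - fw$yield
  sig <- problem$obs_se
  if (!is.na(problem$tcod_meas)) {
    r <- c(r, problem$tcod_meas - fw$tcod_out)
    sig <- c(sig, problem$tcod_weight)
  }
  attr(r, "sigma") <- sig
  r
}

#' Weighted least-squares objective
#'
#' `S = sum(r_i^2 / sigma_i)` (the printed weighting, default) or
#' `S = sum(r_i^2 / sigma_i^2)` (classical inverse-variance weighting),
#' over the methane-curve residuals and the optional COD residual.
#'
#' @inheritParams calibration_residuals
#' @return scalar objective value `S >= 0`.
#' @export
#' @examples
#' ## two residuals (1, 2) with sigma (1, 2):
#' ## printed form 1 + 2 = 3; classical form 1 + 1 = 2
calibration_objective <- function(Pi, problem) {
  r <- calibration_residuals(Pi, problem)
  sig <- attr(r, "sigma")
  if (any(sig <= 0)) stop("all sigma must be > 0", call. = FALSE)
  if (problem$weighting == "printed") sum(r^2 / sig) else sum(r^2 / sig^2)
}

#' Differential evolution, DE/rand/1/bin
#'
#' The classic strategy: for each target vector a mutant
#' `v = x_r1 + F (x_r2 - x_r3)` is built from three distinct random
#' population members, crossed binomially with rate `CR` (one forced
#' dimension), reflected back into the bounds, and kept if it does not
#' worsen the objective. Terminates when the population objective spread
#' `max(f) - min(f)` falls below `tol` (default 4e-3) or after `max_gen`
#' generations. Fully seed-reproducible.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper finite bounds.
#' @param settings list overriding any of `NP` (population, default
#'   `15 * dim`, minimum 4), `F` (0.8), `CR` (0.9), `max_gen` (200),
#'   `tol` (4e-3), `seed` (required for reproducibility, default 1).
#' @return list with `par`, `value`, `trace` (best objective per
#'   generation), `generations`, `converged`, and the evaluated population.
#' @export
#' @examples
#' de_rand_1_bin(function(x) sum(x^2), rep(-5, 4), rep(5, 4),
#'               settings = list(seed = 1))$value
de_rand_1_bin <- function(fn, lower, upper, settings = list()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(c(lower, upper))),
            all(lower < upper))
  s <- utils::modifyList(list(NP = max(4, 15 * d), F = 0.8, CR = 0.9,
                              max_gen = 200, tol = 4e-3, seed = 1),
                         settings)
  if (s$NP < 4) stop("population size must be >= 4", call. = FALSE)
  set.seed(s$seed)
  NP <- s$NP
  pop <- matrix(stats::runif(NP * d, rep(lower, each = NP),
                             rep(upper, each = NP)), nrow = NP)
  f <- apply(pop, 1, fn)
  trace <- min(f)
  gen <- 0
  reflect <- function(x) {
    for (k in seq_len(d)) {
      while (x[k] < lower[k] || x[k] > upper[k]) {
        if (x[k] < lower[k]) x[k] <- 2 * lower[k] - x[k]
        if (x[k] > upper[k]) x[k] <- 2 * upper[k] - x[k]
      }
    }
    x
  }
  while (gen < s$max_gen && (max(f) - min(f)) >= s$tol) {
    gen <- gen + 1
    for (i in seq_len(NP)) {
      r <- sample(setdiff(seq_len(NP), i), 3)
      v <- pop[r[1], ] + s$F * (pop[r[2], ] - pop[r[3], ])
      j_force <- sample.int(d, 1)
      cross <- stats::runif(d) < s$CR
      cross[j_force] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- reflect(u)
      fu <- fn(u)
      if (fu <= f[i]) {
        pop[i, ] <- u
        f[i] <- fu
      }
    }
    trace <- c(trace, min(f))
  }
  best <- which.min(f)
  list(par = pop[best, ], value = f[best], trace = trace,
       generations = gen, converged = (max(f) - min(f)) < s$tol,
       population = pop, objectives = f)
}

#' Calibrate influent composition against BMP observations
#'
#' Runs DE/rand/1/bin on the weighted least-squares objective with the
#' configured number of independent restarts (seeds `seed, seed + 1, ...`),
#' returns the best parameter vector with its forward curve, recovered
#' reactor-output state and cross-restart agreement (maximum relative
#' spread of the recovered parameters across restarts).
#'
#' @param problem a `calibration_problem`.
#' @param seed base random seed.
#' @return list of class `calibration_result`: `par` (named), `value`,
#'   `residuals`, `fitted_curve`, `ar_output`, `tcod_out`, `trace`,
#'   `restart_values`, `restart_pars`, `restart_spread`, `weighting`.
#' @export
calibrate_influent <- function(problem, seed = 1) {
  stopifnot(inherits(problem, "calibration_problem"))
  fn <- function(x) calibration_objective(x, problem)
  runs <- lapply(seq_len(problem$restarts), function(k) {
    st <- utils::modifyList(problem$settings, list(seed = seed + k - 1))
    de_rand_1_bin(fn, problem$lower, problem$upper, settings = st)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(vals)))
    stop("no calibration restart converged to a finite objective",
         call. = FALSE)
  best <- runs[[which.min(vals)]]
  pars <- do.call(rbind, lapply(runs, `[[`, "par"))
  spread <- if (nrow(pars) > 1) {
    rng <- apply(pars, 2, function(x) diff(range(x)))
    scale <- pmax(abs(apply(pars, 2, stats::median)), 1e-8)
    max(rng / scale)
  } else 0
  fw <- forward_model(best$par, problem)
  res <- calibration_residuals(best$par, problem)
  out <- list(par = stats::setNames(best$par, problem$free_names),
              value = best$value, residuals = res,
              fitted_curve = fw$curve, ar_output = fw$ar$final_state,
              tcod_out = fw$tcod_out, trace = best$trace,
              generations = best$generations, converged = best$converged,
              restart_values = vals, restart_pars = pars,
              restart_spread = spread, weighting = problem$weighting,
              seed = seed)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Influent calibration (DE/rand/1/bin,", x$weighting, "weighting)\n")
  cat("  S =", signif(x$value, 6), "after", x$generations, "generations",
      if (x$converged) "(converged)" else "(max generations)", "\n")
  print(signif(x$par, 6))
  if (length(x$restart_values) > 1)
    cat("  restart objective values:",
        paste(signif(x$restart_values, 4), collapse = ", "),
        "; parameter spread", signif(x$restart_spread, 3), "\n")
  invisible(x)
}
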