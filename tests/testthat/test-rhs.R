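test_that("inlined and modular right-hand sides agree to machine noise", {
  p <- default_params()
  infl <- adm1_influent()
  set.seed(3)
  for (form in c("dae", "ode")) {
    for (mode in c("continuous", "batch")) {
      cfg <- reactor_config(mode, formulation = form,
                            V_liq = if (mode == "batch") 1 else 3485.4,
                            V_gas = if (mode == "batch") 1.5 else 300)
      y0 <- adm1sim:::.initial_vector(adm1_digested_sludge(), cfg, p)
      fast <- adm1sim:::.make_fast_rhs(infl, cfg, p, form)
      slow <- make_adm1_rhs(infl, cfg, p, form)
      for (i in 1:5) {
        y <- y0 * exp(stats::runif(length(y0), -0.4, 0.4))
        a <- fast(0, y, NULL)[[1]]
        b <- slow(0, y, NULL)[[1]]
        expect_lt(max(abs(a - unname(b)) / pmax(abs(b), 1e-8)), 1e-10)
      }
    }
  }
})

test_that("a dead batch is a fixed point of the dynamics", {
  p <- default_params()
  cfg <- reactor_config("batch", V_liq = 1, V_gas = 1.5)
  st <- adm1_state(S_cat = 0.02, S_an = 0.02)
  out <- system_rhs(st, st, cfg, p)
  expect_lt(max(abs(out$derivatives)), 1e-12)
})

test_that("DAE and ODE formulations agree along a batch trajectory", {
  p <- default_params()
  seed <- ar_reference_output()
  cfgd <- reactor_config("batch", V_liq = 1, V_gas = 1.5, duration = 10,
                         output_dt = 1, formulation = "dae")
  cfgo <- reactor_config("batch", V_liq = 1, V_gas = 1.5, duration = 10,
                         output_dt = 1, formulation = "ode")
  rd <- simulate_bmp(seed, cfgd, p)
  ro <- simulate_bmp(seed, cfgo, p)
  core <- adm1_state_names("core")
  a <- as.matrix(rd$trajectory[core])
  b <- as.matrix(ro$trajectory[core])
  rel <- abs(a - b) / pmax(abs(b), 1e-4)
  expect_lt(max(rel), 0.01)
  ## and the methane accounting agrees too
  expect_equal(rd$cum_ch4_cod, ro$cum_ch4_cod, tolerance = 1e-3)
})

test_that("charge-balance residual stays below tolerance along a DAE run", {
  p <- default_params()
  res <- simulate_bmp(ar_reference_output(),
                      reactor_config("batch", V_liq = 1, V_gas = 1.5,
                                     duration = 5, output_dt = 0.5), p)
  for (i in seq_len(nrow(res$trajectory))) {
    row <- res$trajectory[i, ]
    st <- adm1_state(stats::setNames(as.numeric(row[adm1_state_names()]),
                                     adm1_state_names()))
    S_H <- 10^(-row$pH)
    ion <- ion_concentrations(st, S_H, p)
    resid <- st[["S_cat"]] + (st[["S_IN"]] - ion[["S_nh3"]]) + S_H -
      ion[["S_hco3_ion"]] - ion[["S_ac_ion"]] / 64 -
      ion[["S_pro_ion"]] / 112 - ion[["S_bu_ion"]] / 160 -
      ion[["S_va_ion"]] / 208 - p$K_h2o / S_H - st[["S_an"]]
    expect_lt(abs(resid), 1e-10)
  }
})

test_that("no state component goes negative beyond solver tolerance", {
  res <- coupled_run()
  conc <- as.matrix(res$ar$trajectory[c(adm1_state_names("core"),
                                        adm1_state_names("gas"))])
  expect_gt(min(conc), -1e-8)
  conc_b <- as.matrix(res$bmp$trajectory[c(adm1_state_names("core"),
                                           adm1_state_names("gas"))])
  expect_gt(min(conc_b), -1e-8)
})
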