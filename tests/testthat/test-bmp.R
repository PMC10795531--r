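test_that("replicate endpoint summary matches the reference assay", {
  ends <- bmp_reference_endpoints()$nml
  d <- bmp_dataset(c(0, 11), rbind(rep(0, 6), ends))
  s <- bmp_summary(d)
  expect_equal(s$endpoint$mean_nml, 136)
  expect_equal(s$endpoint$sd_nml, 7.5, tolerance = 0.01)
  expect_equal(s$endpoint$n, 6)
  ## per-VS yield with 1.1 g VS (100 mL x 1.1% TVS)
  expect_equal(s$endpoint$mean_yield, 136 / 1.1)
  expect_equal(yield_per_vs(136, 1.1), 123.6, tolerance = 1e-2)
})

test_that("summaries are replicate-permutation invariant", {
  set.seed(5)
  m <- rbind(0, matrix(cummax(runif(30, 0, 150)), nrow = 5))
  m <- apply(m, 2, cummax)
  d1 <- bmp_dataset(0:5, m)
  d2 <- bmp_dataset(0:5, m[, c(3, 1, 2, 6, 5, 4)])
  expect_equal(bmp_summary(d1)$per_day[c("mean", "sd", "se")],
               bmp_summary(d2)$per_day[c("mean", "sd", "se")])
})

test_that("dataset validation catches malformed curves", {
  expect_error(bmp_dataset(c(0, 1), rbind(c(0, 0), c(5, -1))),
               "non-decreasing")
  expect_error(bmp_dataset(c(1, 2), rbind(c(0, 0), c(5, 6))), "start at 0")
  expect_error(bmp_dataset(c(0, 1), rbind(c(0, 0), c(5, 6)),
                           working_volume = 0), "positive")
  ## identical replicates summarize with zero sd
  d <- bmp_dataset(c(0, 1), cbind(c(0, 10), c(0, 10)))
  expect_equal(bmp_summary(d)$per_day$sd, c(0, 0))
})

test_that("COD removal and theoretical methane follow the definitions", {
  expect_equal(cod_removal(21903, 16820), 23.2)
  expect_equal(cod_removal(21903, 15680), 28.4)
  expect_equal(cod_removal(100, 100), 0)
  expect_warning(cod_removal(100, 110), "outside")
  expect_error(cod_removal(0, 10), "positive")
  expect_equal(theoretical_methane(1), 350)
  expect_equal(theoretical_methane(0), 0)
  ## reference replicate R1: 23.2% of 21.903 g/L in 0.1 L
  removed <- (21903 - 16820) / 1000 * 0.1
  expect_equal(theoretical_methane(removed), 177.9, tolerance = 1e-3)
  ## observed 124 NmL is below the theoretical equivalent
  expect_lt(124 / theoretical_methane(removed), 1)
})

test_that("synthetic generator is deterministic and zero-noise exact", {
  curve <- coupled_daily_yield()$yield * 1.1   # NmL on days 0..11
  d0 <- generate_synthetic_bmp(adm1_influent(), noise_sd = 0,
                               n_replicates = 3, seed = 9,
                               true_curve = curve)
  expect_equal(unname(d0$curves[, 1]), curve)
  expect_equal(unname(d0$curves[, 3]), curve)
  d1 <- generate_synthetic_bmp(adm1_influent(), noise_sd = 3,
                               n_replicates = 6, seed = 4,
                               true_curve = curve)
  d2 <- generate_synthetic_bmp(adm1_influent(), noise_sd = 3,
                               n_replicates = 6, seed = 4,
                               true_curve = curve)
  expect_identical(d1$curves, d2$curves)
  expect_false(identical(d1$curves,
                         generate_synthetic_bmp(adm1_influent(),
                                                noise_sd = 3,
                                                n_replicates = 6, seed = 5,
                                                true_curve = curve)$curves))
  expect_error(generate_synthetic_bmp(adm1_influent(), true_curve = curve),
               "seed")
})

test_that("generator noise calibrates to the requested replicate sd", {
  curve <- coupled_daily_yield()$yield * 1.1
  ## use the steeply rising days, where daily increments (>12 NmL) dwarf
  ## the noise so the monotonicity clamp never bites; on the plateau the
  ## clamp necessarily shrinks the spread below the nominal sd
  mid_days <- 1:4
  sds <- vapply(1:200, function(s) {
    d <- generate_synthetic_bmp(adm1_influent(), noise_sd = 3,
                                n_replicates = 6, seed = s,
                                true_curve = curve)
    mean(apply(d$curves[mid_days + 1, ], 1, sd))
  }, numeric(1))
  expect_equal(mean(sds), 3, tolerance = 0.1)
})

test_that("BMP CSV dialect round-trips", {
  curve <- coupled_daily_yield()$yield * 1.1
  d <- generate_synthetic_bmp(adm1_influent(), noise_sd = 2,
                              n_replicates = 4, seed = 2,
                              true_curve = curve)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(day = d$days, d$curves), f, row.names = FALSE)
  d2 <- read_bmp_csv(f)
  expect_equal(d2$curves, d$curves, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(read_bmp_csv(f, working_volume = -1), "positive")
})
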