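test_that("rate_law_spec enforces substrate/product admissibility", {
  expect_error(rate_law_spec("AA", "linear_inhibition"), "not admissible")
  expect_error(rate_law_spec("HA", "monod"), "not admissible")
  sp <- rate_law_spec("AA", "monod_toxlimit", fixed = list(ki = 330))
  expect_setequal(sp$free, c("mu_max", "ks"))
  expect_error(rate_law_spec("AA", "monod", fixed = list(ki = 1)),
               "not in family")
})

test_that("noise-free rate-law data round-trips through the fitter", {
  s <- seq(0, 257, length.out = 12)
  truth <- table1_truth()
  d <- grid_dataset("AA", s, monod(s, truth$mu_max, truth$ks_aa), reps = 3)
  f <- fit_rate_law(d, rate_law_spec("AA", "monod"))
  expect_true(f$converged)
  expect_equal(f$estimates[["mu_max"]], truth$mu_max, tolerance = 1e-3)
  expect_equal(f$estimates[["ks"]], truth$ks_aa, tolerance = 1e-3)

  ha <- seq(5, 85, length.out = 12)
  d2 <- grid_dataset("HA", ha,
                     linear_inhibition(ha, truth$mu_max, truth$k_ha))
  f2 <- fit_rate_law(d2, rate_law_spec("HA", "linear_inhibition"))
  expect_equal(f2$estimates[["k"]], truth$k_ha, tolerance = 1e-3)
  expect_equal(f2$sse, 0, tolerance = 1e-10)
})

test_that("underdetermined and degenerate fits are rejected", {
  d1 <- grid_dataset("AA", 10, 0.1)
  expect_error(fit_rate_law(d1, rate_law_spec("AA", "monod")),
               "underdetermined")
  d0 <- grid_dataset("AA", c(1, 2, 3, 4), rep(0, 4))
  expect_error(fit_rate_law(d0, rate_law_spec("AA", "monod")), "degenerate")
})

test_that("the conditioning Monod factor enters the BA fit", {
  truth <- table1_truth()
  ba <- seq(0.4, 128, length.out = 12)
  d <- grid_dataset("BA", ba,
                    truth$mu_max * toxicity_factor(ba, truth$ki_ba))
  d$aa0 <- 1.6  # fixed co-substrate level
  d$mu <- d$mu * 1.6 / (4.7 + 1.6)
  f <- fit_rate_law(d, rate_law_spec("BA", "toxlimit",
                                     conditioning = list(compound = "AA",
                                                         ks = 4.7)))
  expect_equal(f$estimates[["mu_max"]], truth$mu_max, tolerance = 1e-3)
  expect_equal(f$estimates[["ki"]], truth$ki_ba, tolerance = 1e-2)
})

test_that("model selection ranks the generating family first", {
  truth <- table1_truth()
  designs <- table2_designs()
  set.seed(11)
  aa <- rbind(synth_mu_dataset(designs$A, truth, noise_model(seed = 21)),
              synth_mu_dataset(designs$B, truth, noise_model(seed = 22)))
  ranked <- select_rate_law(aa, list(
    rate_law_spec("AA", "monod"),
    rate_law_spec("AA", "haldane"),
    rate_law_spec("AA", "monod_toxlimit", fixed = list(ki = 330))))
  expect_equal(ranked[[1]]$spec$family, "monod_toxlimit")

  ha <- synth_mu_dataset(designs$G, truth, noise_model(seed = 23))
  ranked2 <- select_rate_law(ha, list(
    rate_law_spec("HA", "toxlimit"),
    rate_law_spec("HA", "linear_inhibition")))
  expect_equal(ranked2[[1]]$spec$family, "linear_inhibition")
})

test_that("ties between identical candidates break by parameter count", {
  s <- seq(1, 100, length.out = 10)
  truth <- table1_truth()
  d <- grid_dataset("AA", s, monod_toxlimit(s, 0.24, 3.8, 330))
  # same family twice: once with ki free (3 params), once fixed (2 params)
  ranked <- select_rate_law(d, list(
    rate_law_spec("AA", "monod_toxlimit"),
    rate_law_spec("AA", "monod_toxlimit", fixed = list(ki = 330))))
  expect_lte(ranked[[1]]$n_free, ranked[[2]]$n_free)
  expect_lte(ranked[[1]]$sse, ranked[[2]]$sse + 1e-8)
})

test_that("zero-noise simultaneous calibration recovers all four parameters", {
  truth <- table1_truth()
  d <- synth_calibration_dataset(truth, noise_model(mu_sd = 0, seed = 1))
  cal <- calibrate_combined(d, start = update_params(truth, list(
    mu_max = 0.3, ks_aa = 2, ki_ba = 100, k_ha = 0.02)))
  expect_true(cal$converged)
  expect_equal(cal$estimates[["mu_max"]], truth$mu_max, tolerance = 1e-3)
  expect_equal(cal$estimates[["ks_aa"]], truth$ks_aa, tolerance = 1e-3)
  expect_equal(cal$estimates[["ki_ba"]], truth$ki_ba, tolerance = 1e-3)
  expect_equal(cal$estimates[["k_ha"]], truth$k_ha, tolerance = 1e-3)
  expect_equal(unname(cal$fixed["ki_aa"]), 330)
})

test_that("single-experiment calibration warns about identifiability", {
  truth <- table1_truth()
  d <- synth_mu_dataset(table2_designs()$G, truth, noise_model(seed = 4))
  expect_warning(cal <- calibrate_combined(d, start = truth),
                 "identifiab")
  expect_s3_class(cal, "combined_fit")
})

test_that("two-stage flow selects the right laws and uses stage-1 starts", {
  truth <- table1_truth()
  d <- synth_calibration_dataset(truth, noise_model(seed = 7))
  cal <- calibrate_two_stage(d)
  expect_equal(cal$stage1$AA[[1]]$spec$family, "monod_toxlimit")
  expect_equal(cal$stage1$BA[[1]]$spec$family, "toxlimit")
  expect_equal(cal$stage1$HA[[1]]$spec$family, "linear_inhibition")
  # the BA conditioning uses the stage-1 AA half-saturation estimate
  expect_equal(cal$stage1$BA[[1]]$spec$conditioning$ks,
               cal$stage1$AA[[1]]$estimates[["ks"]])
  # recovery within the reported 95% CI half-widths
  s2 <- cal$stage2
  expect_lt(abs(s2$estimates[["mu_max"]] - truth$mu_max), 0.01)
  expect_lt(abs(s2$estimates[["ks_aa"]] - truth$ks_aa), 0.9)
  expect_lt(abs(s2$estimates[["ki_ba"]] - truth$ki_ba), 5.7)
  expect_lt(abs(s2$estimates[["k_ha"]] - truth$k_ha), 1.3e-3)
  expect_error(calibrate_two_stage(d[d$experiment_id != "G", ]),
               "missing: G")
})

test_that("repeated-seed recovery keeps median errors within the printed CIs", {
  truth <- table1_truth()
  errs <- sapply(1:50, function(s) {
    d <- synth_calibration_dataset(truth, noise_model(seed = 3000 + s))
    est <- calibrate_two_stage(d)$stage2$estimates
    c(mu_max = abs(est[["mu_max"]] - truth$mu_max),
      ks_aa = abs(est[["ks_aa"]] - truth$ks_aa))
  })
  expect_lt(stats::median(errs["mu_max", ]), 0.01)
  expect_lt(stats::median(errs["ks_aa", ]), 0.9)
})
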