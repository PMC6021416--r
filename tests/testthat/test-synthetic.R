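test_that("the design registry reproduces the printed experimental grid", {
  designs <- table2_designs()
  expect_length(designs, 9)
  expect_setequal(names(designs), LETTERS[1:9])
  expect_equal(range(designs$A$varied$levels), c(0, 257))
  expect_equal(range(designs$B$varied$levels), c(0, 750))
  expect_equal(range(designs$E$varied$levels), c(0.4, 128))
  expect_equal(range(designs$F$varied$levels), c(0, 160))
  expect_equal(range(designs$G$varied$levels), c(5, 184))
  # fixed co-substrates
  expect_equal(designs$E$fixed[["aa"]], 1.6)
  expect_equal(designs$F$fixed[["aa"]], 6)
  expect_equal(designs$G$fixed[["aa"]], 80)
  for (id in c("A", "B", "D", "E", "F", "G", "H", "I"))
    expect_equal(designs[[id]]$fixed[["etoh"]], 343)
  # exclusions from fitting
  expect_false(designs$C$fit_eligible)
  expect_false(designs$D$fit_eligible)
  expect_true(all(vapply(designs[c("A", "B", "E", "F", "G")],
                         `[[`, logical(1), "fit_eligible")))
})

test_that("synthetic growth-rate data are exact at zero noise and seeded", {
  truth <- table1_truth()
  design <- table2_designs()$G
  d0 <- synth_mu_dataset(design, truth, noise_model(mu_sd = 0, seed = 1))
  expect_equal(nrow(d0), 12 * 3)
  expect_equal(d0$mu,
               combined_mu(aa = d0$aa0, ba = d0$ba0, ha = d0$ha0,
                           params = truth))
  a <- synth_mu_dataset(design, truth, noise_model(seed = 42))
  b <- synth_mu_dataset(design, truth, noise_model(seed = 42))
  expect_identical(a, b)
  c2 <- synth_mu_dataset(design, truth, noise_model(seed = 43))
  expect_false(identical(a$mu, c2$mu))
  expect_true(all(a$mu >= 0))
})

test_that("noise averages out over many replicates (law of large numbers)", {
  truth <- table1_truth()
  design <- table2_designs(n_levels = 2, replicates = 5000)$G
  d <- synth_mu_dataset(design, truth, noise_model(mu_sd = 0.01, seed = 8))
  lv <- design$varied$levels[1]
  model <- combined_mu(aa = 80, ba = 0, ha = lv, params = truth)
  got <- mean(d$mu[d$ha0 == lv])
  expect_lt(abs(got - model), 3 * 0.01 / sqrt(5000))
})

test_that("synthetic plates rebuild the assay geometry", {
  sp <- synth_plate(table2_designs()$G, table1_truth(),
                    noise = noise_model(seed = 3))
  lay <- sp$layout
  # outer ring is evaporation buffer
  ring <- lay$row %in% c("A", "H") | lay$col %in% c(1, 12)
  expect_true(all(lay$role[ring] == "evaporation_buffer"))
  expect_equal(sum(lay$role == "sample"), 12 * 3)
  expect_gte(sum(lay$role == "uninoculated_blank"), 3)
  # replicate indices unique within a condition
  samp <- lay[lay$role == "sample", ]
  expect_true(all(tapply(samp$replicate, samp$condition_id,
                         function(r) !anyDuplicated(r))))
  expect_equal(sp$plate$time, seq(0, 90, 0.25))
  # a design too large for the interior is rejected
  expect_error(synth_plate(table2_designs(n_levels = 25)$G, table1_truth()),
               "design too large")
})

test_that("plate generation is deterministic and OD stays near baseline bounds", {
  truth <- table1_truth()
  a <- synth_plate(table2_designs()$G, truth, noise = noise_model(seed = 6))
  b <- synth_plate(table2_designs()$G, truth, noise = noise_model(seed = 6))
  expect_identical(a$plate, b$plate)
  od <- as.matrix(a$plate[-1])
  expect_true(all(od > 0.05 - 5 * 0.005))
})

test_that("the full pipeline recovers the generating growth rates", {
  truth <- table1_truth()
  sp <- synth_plate(table2_designs()$G, truth, noise = noise_model(seed = 3))
  res <- fit_growth_rates(sp$plate, sp$layout)
  expect_equal(nrow(res$dataset), 36)
  d <- res$dataset
  gen <- combined_mu(aa = d$aa0, ba = d$ba0, ha = d$ha0, params = truth)
  ok <- gen >= 0.05
  # replicate-mean recovery per condition within 5%
  cm <- tapply(d$mu[ok], d$ha0[ok], mean)
  gm <- tapply(gen[ok], d$ha0[ok], mean)
  expect_lt(max(abs(cm - gm) / gm), 0.05)
  # every single well within 12% (per-well scatter at this OD noise)
  expect_lt(max(abs(d$mu[ok] - gen[ok]) / gen[ok]), 0.12)
  # fully inhibited conditions flagged as no growth
  expect_true(all(d$mu[gen == 0] == 0))
})

test_that("blank wells carry noise only, leaving corrected samples unbiased", {
  truth <- table1_truth()
  sp <- synth_plate(table2_designs()$G, truth,
                    noise = noise_model(od_sd = 0, seed = 1))
  blanks <- sp$layout$well[sp$layout$role == "uninoculated_blank"]
  for (w in blanks) expect_true(all(sp$plate[[w]] == 0.05))
  dod <- blank_correct(sp$plate, sp$layout)
  # noiseless generation: corrected signal is exactly the Richards dOD
  w1 <- sp$layout$well[sp$layout$role == "sample"][1]
  mu <- combined_mu(aa = 80, ba = 0, ha = 5, params = truth)
  y <- richards_curve(sp$plate$time, mu, 10, 2, 1)
  expect_equal(dod[[w1]], 0.5 * exp(y - 2), tolerance = 1e-12)
})

test_that("validation runs start from the tracked conditions and subsample", {
  runs <- synth_validation_runs()
  expect_named(runs, c("high_aa", "low_aa"))
  expect_equal(unname(runs$high_aa$initial[c("etoh", "aa", "ba", "ha")]),
               c(308, 83, 0, 0))
  expect_equal(unname(runs$low_aa$initial[c("etoh", "aa", "ba", "ha")]),
               c(220, 30, 0, 0))
  expect_equal(nrow(runs$high_aa$samples), 10)
  # subsample rows are exact rows of the dense trajectory
  m <- merge(as.data.frame(runs$high_aa$samples),
             as.data.frame(runs$high_aa$trajectory), by = "t")
  expect_equal(nrow(m), 10)
  expect_equal(m$ha.x, m$ha.y)
})
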