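test_that("growth terms: zeros, symmetry and weight normalisation", {
  cfg <- sim_config()
  g0 <- growth_terms(sim_state(300, 0, 0, 0, x = 10), cfg)
  expect_equal(g0$mu1, 0)
  expect_equal(g0$mu2, 0)
  expect_equal(g0$w1 + g0$w2, 0)  # 0/0 convention
  expect_equal(g0$r1 + g0$r2, 0)

  # symmetric state: equal substrate saturation -> equal weights
  p <- cfg$params
  sym <- sim_state(300, p$ks_aa, p$ks_ba, 0, x = 10)
  gs <- growth_terms(sym, cfg)
  expect_equal(gs$mu1, gs$mu2, tolerance = 1e-12)
  expect_equal(gs$w1, 0.5)

  # any growing state: weights sum to one
  g <- growth_terms(sim_state(300, 50, 20, 10, x = 10), cfg)
  expect_equal(g$w1 + g$w2, 1)
  # observed growth rate never exceeds the faster reaction
  expect_lte(g$w1 * g$mu1 + g$w2 * g$mu2, max(g$mu1, g$mu2))
})

test_that("derivatives vanish without biomass or under full inhibition", {
  cfg <- sim_config()
  expect_true(all(derivatives(sim_state(300, 80, 10, 5, x = 0), cfg) == 0))
  ha_stop <- 1 / cfg$params$k_ha
  expect_true(all(derivatives(sim_state(300, 80, 10, ha_stop, x = 10),
                              cfg) == 0))
})

test_that("instantaneous dissolved-carbon change is zero at any state", {
  cfg <- sim_config()
  set.seed(5)
  for (i in 1:20) {
    st <- sim_state(runif(1, 0, 400), runif(1, 0, 300), runif(1, 0, 150),
                    runif(1, 0, 80), x = runif(1, 1, 500))
    d <- derivatives(st, cfg)
    dC <- 2 * d[["etoh"]] + 2 * d[["aa"]] + 4 * d[["ba"]] + 6 * d[["ha"]]
    expect_equal(dC, 0, tolerance = 1e-12)
  }
})

test_that("halving the yield doubles every dissolved-species derivative", {
  st <- sim_state(300, 80, 20, 5, x = 50)
  d1 <- derivatives(st, sim_config(y_etoh = 2.75))
  d2 <- derivatives(st, sim_config(y_etoh = 2.75 / 2))
  sp <- c("etoh", "aa", "ba", "ha", "h2")
  expect_equal(d2[sp], 2 * d1[sp], tolerance = 1e-12)
  expect_equal(d2[["x"]], d1[["x"]])  # biomass growth is yield-free
})

test_that("the high-acetate validation scenario has the reported shape", {
  traj <- simulate_chain_elongation(sim_state(308, 83, 0, 0, x = 10),
                                    sim_config())
  expect_equal(traj$t[1], 0)
  expect_equal(traj$etoh[1], 308)
  # acetate is consumed overall
  expect_lt(traj$aa[nrow(traj)], traj$aa[1])
  # butyrate rises to an interior peak, then falls
  ipk <- which.max(traj$ba)
  expect_gt(ipk, 1)
  expect_lt(ipk, nrow(traj))
  expect_gt(max(traj$ba), 5)
  expect_lt(traj$ba[nrow(traj)], max(traj$ba))
  # hexanoate accumulates monotonically
  expect_true(all(diff(traj$ha) >= -1e-9))
  # biomass only grows (no decay term)
  expect_true(all(diff(traj$x) >= -1e-9))
})

test_that("dissolved carbon is conserved along trajectories", {
  for (init in list(sim_state(308, 83, 0, 0, x = 10),
                    sim_state(220, 30, 0, 0, x = 10))) {
    traj <- simulate_chain_elongation(init, sim_config())
    carbon <- carbon_total(traj)
    expect_lt(max(abs(carbon - carbon[1])) / carbon[1], 1e-6)
  }
})

test_that("hexanoate above the inhibition limit freezes the culture", {
  top_ha <- max(table2_designs()$G$varied$levels)  # 184 mM
  traj <- simulate_chain_elongation(sim_state(343, 80, 0, top_ha, x = 10),
                                    sim_config())
  expect_equal(max(abs(traj$aa - 80)), 0, tolerance = 1e-10)
  expect_equal(max(abs(traj$x - 10)), 0, tolerance = 1e-10)
})

test_that("early growth is exponential at the initial-state rate", {
  cfg <- sim_config()
  init <- sim_state(343, 250, 0, 0, x = 10)  # AA >> ks_aa, no products
  g <- growth_terms(init, cfg)
  # the limit is instantaneous: as soon as butyrate appears, the second
  # reaction dilutes the observed weighted rate below mu1, so use a fine
  # first interval
  fine <- sim_config(t_end = 1, dt_out = 0.01)
  traj <- simulate_chain_elongation(init, fine)
  rate <- log(traj$x[2] / traj$x[1]) / (traj$t[2] - traj$t[1])
  expect_equal(rate, g$mu1, tolerance = 5e-3)
  # and the weighted rate never exceeds the faster reaction along the way
  expect_true(all(traj$w1 * traj$mu1 + traj$w2 * traj$mu2 <=
                    pmax(traj$mu1, traj$mu2) + 1e-12))
})

test_that("tightening solver tolerances leaves the final state unchanged", {
  init <- sim_state(308, 83, 0, 0, x = 10)
  a <- simulate_chain_elongation(init, sim_config(rtol = 1e-6, atol = 1e-6))
  b <- simulate_chain_elongation(init, sim_config(rtol = 1e-7, atol = 1e-7))
  fa <- unlist(a[nrow(a), c("etoh", "aa", "ba", "ha", "x")])
  fb <- unlist(b[nrow(b), c("etoh", "aa", "ba", "ha", "x")])
  expect_lt(max(abs(fa - fb) / pmax(abs(fb), 1)), 1e-3)
})

test_that("lag removal shifts and trims the time axis", {
  traj <- tibble::tibble(t = seq(0, 90, 0.25), v = seq(0, 90, 0.25)^2)
  expect_equal(remove_lag(traj, 0), traj)
  out <- remove_lag(traj, 10)
  expect_equal(out$t[1], 0)
  expect_equal(max(out$t), 80)
  expect_equal(out$v[1], 100)
  expect_error(remove_lag(traj, 100), "exceeds")
})

test_that("Henderson-Hasselbalch speciation", {
  expect_equal(undissociated_fraction(10, ph = 4.88, pka = 4.88), 5)
  expect_equal(undissociated_fraction(0, ph = 7, pka = 4.88), 0)
  # near-neutral pH leaves only a trace protonated
  expect_equal(undissociated_fraction(91.3, ph = 7.85, pka = 4.88), 0.0977,
               tolerance = 1e-3)
})
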