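test_that("with cleavage off the simulation reaches the two-site equilibrium", {
  sc <- kinetic_scheme(k_on = 0.1, k_off = 0.06, k_cut = 0, P0 = 20,
                       batches = data.frame(name = "s", S0 = 2, D0 = 50,
                                            t_add = -2000))
  tr <- simulate_cleavage_kinetics(sc, c(-2000, 0))
  eq <- tr[nrow(tr), ]
  Kd <- sc$k_off / sc$k_on
  theta2 <- fraction_dimer_bound(eq$P, Kd)
  sim_frac <- eq$s.SP2 / (eq$s.S + eq$s.SP + eq$s.SP2)
  expect_lt(abs(sim_frac - theta2), 1e-6)
  # singly bound fraction matches 2 theta (1 - theta)
  theta <- fraction_single_bound(eq$P, Kd)
  expect_lt(abs(eq$s.SP / (eq$s.S + eq$s.SP + eq$s.SP2) -
                2 * theta * (1 - theta)), 1e-6)
  # decoys follow the plain hyperbola
  expect_lt(abs(eq$s.DP / (eq$s.D + eq$s.DP) - theta), 1e-6)
})

test_that("protein and DNA pools are conserved throughout", {
  sc <- kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 2, P0 = 100,
                       batches = data.frame(name = c("a", "b"),
                                            S0 = c(2, 2), D0 = c(200, 200),
                                            t_add = c(-30, 10)))
  tr <- simulate_cleavage_kinetics(sc, seq(-30, 60, by = 5))
  ct <- conserved_totals(tr, sc)
  expect_lt(max(abs(ct$protein - 100)) / 100, 1e-8)
  after_a <- ct$time >= -30
  expect_lt(max(abs(ct$a.sites[after_a] - 2)) / 2, 1e-8)
  after_b <- ct$time >= 10
  expect_lt(max(abs(ct$b.sites[after_b] - 2)) / 2, 1e-8)
})

test_that("irreversible binding traps protein on the first substrate", {
  # protein is sub-stoichiometric to the first batch's sites, so with
  # k_off = 0 none is left for the challenger
  sc <- kinetic_scheme(k_on = 1, k_off = 0, k_cut = 5, P0 = 10,
                       batches = data.frame(name = c("first", "second"),
                                            S0 = c(1, 1), D0 = c(50, 50),
                                            t_add = c(-60, 0)))
  tr <- simulate_cleavage_kinetics(sc, c(0, 30, 60))
  u <- substrate_utilization(tr, sc)
  expect_lt(u$second[u$time == 60], 1e-4)   # never cut: no exchange
  expect_gt(u$first[u$time == 60], 1)       # only pre-assembled dimers cut
})

test_that("trap kinetics are biphasic with order-of-addition asymmetry", {
  sc <- kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 2, P0 = 100,
                       batches = data.frame(name = c("first", "second"),
                                            S0 = c(2, 2), D0 = c(200, 200),
                                            t_add = c(-30, 0)))
  tg <- c(0, 0.5, 1, 2, 3, 5, 8, 12, 20, 30, 45, 60)
  u <- substrate_utilization(simulate_cleavage_kinetics(sc, tg), sc)

  # utilization is monotone non-decreasing at every grid point
  expect_true(all(diff(u$first) >= -1e-9))
  expect_true(all(diff(u$second) >= -1e-9))

  # biphasic: a two-phase fit separates a fast and a slow rate
  fit <- two_phase_fit(u$time, u$first)
  expect_false(fit$degenerate)
  expect_gt(fit$k1 / fit$k2, 50)

  # the substrate pre-incubated with protein is cut faster than the
  # challenger added at reaction start
  expect_gt(u$first[u$time == 5], 5 * u$second[u$time == 5])
  expect_gt(u$first[u$time == 60], u$second[u$time == 60])

  # the fast-phase amplitude reflects the pre-assembled doubly bound pool
  pre <- simulate_cleavage_kinetics(
    kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 0, P0 = 100,
                   batches = data.frame(name = "first", S0 = 2, D0 = 200,
                                        t_add = -30)),
    c(-30, 0))
  sp2_frac <- pre$first.SP2[pre$time == 0] / 2
  expect_lt(abs(fit$A1 / 100 - sp2_frac), 0.1)
})

test_that("boosting the second binding step raises the fast-phase amplitude", {
  mk <- function(boost) {
    sc <- kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 2, P0 = 100,
                         batches = data.frame(name = "s", S0 = 2, D0 = 200,
                                              t_add = -30),
                         dimer_on_boost = boost)
    u <- substrate_utilization(
      simulate_cleavage_kinetics(sc, c(0, 1, 2, 3, 5)), sc)
    u$s[u$time == 3]  # early cleavage ~ fast-phase amplitude
  }
  expect_gt(mk(5), mk(1))
})

test_that("utilization limits and schedule bookkeeping are exact", {
  sc <- kinetic_scheme(k_on = 2, k_off = 0.5, k_cut = 10, P0 = 500,
                       batches = data.frame(name = "s", S0 = 1, D0 = 0,
                                            t_add = 0))
  tr <- simulate_cleavage_kinetics(sc, c(0, 50))
  u <- substrate_utilization(tr, sc)
  expect_equal(u$s[u$time == 0], 0)
  expect_gt(u$s[u$time == 50], 99.9)  # excess protein: all substrate reachable
})
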