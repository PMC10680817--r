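test_that("random connectomes hit their density limits and binomial expectation", {
  full <- er_connectome(10, 1, seed = 1)
  expect_equal(nrow(full$edges), 45L)
  expect_equal(avg_degree(full), 9)
  empty <- er_connectome(10, 0, seed = 1)
  expect_equal(nrow(empty$edges), 0L)

  counts <- vapply(1:30, function(s) nrow(er_connectome(64, 0.4, seed = s)$edges),
                   numeric(1))
  expected <- 0.4 * choose(64, 2)  # 806.4
  se <- sqrt(choose(64, 2) * 0.4 * 0.6 / 30)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("connectome construction enforces a simple undirected graph", {
  expect_error(connectome(5, rbind(c(1, 1))), "self-loops")
  expect_error(connectome(5, rbind(c(1, 6))), "out of range")
  expect_error(connectome(5, rbind(c(1, 2), c(2, 1))), "duplicate")
  g <- connectome(4, rbind(c(3, 1), c(2, 4)))
  expect_equal(g$edges, cbind(c(1L, 2L), c(3L, 4L)))
  expect_equal(g$pedge, 2 * 2 / (4 * 3))
})

test_that("free spins reproduce binomial synchrony and every value sits on the parity grid", {
  g <- connectome(16, matrix(integer(0), ncol = 2))
  cfg <- sim_config(seed = 5, lam0 = 0, n_steps = 4000, flips_per_step = 32)
  s <- metropolis_run(g, cfg)
  expect_length(s, 4000)
  expect_true(all(abs(s * 16 - round(s * 16)) < 1e-12))
  expect_true(all(round(s * 16) %% 2 == 0))
  mom <- empirical_moments(s)
  # free spins: m2 = 1/16, Monte-Carlo error ~ sqrt(var(s^2)/T_eff)
  expect_lt(abs(mom$m2 - 1 / 16), 0.01)
})

test_that("a zero-energy flip is always accepted: the free chain moves every attempt", {
  # with no edges every proposal has dlogW = 0; one attempt per step must
  # flip exactly one spin, shifting synchrony by exactly 2/n each step
  g <- connectome(8, matrix(integer(0), ncol = 2))
  cfg <- sim_config(seed = 9, lam0 = 0, n_steps = 500, flips_per_step = 1)
  s <- metropolis_run(g, cfg)
  expect_true(all(abs(abs(diff(s)) - 2 / 8) < 1e-12))
})

test_that("the stationary distribution matches exact Boltzmann weights on tiny graphs", {
  withr::with_seed(41, {
    for (trial in 1:2) {
      g <- er_connectome(6, 0.6, seed = 100 + trial)
      cfg <- sim_config(seed = 200 + trial, lam0 = 2.5, n_steps = 30000,
                        flips_per_step = 12, burn_in = 200)
      j_edge <- 2 * cfg$lam0 / g$n_nodes^2
      exact <- brute_force_graph_pmf(g, j_edge)
      s <- metropolis_run(g, cfg)
      emp <- tabulate(match(round(s * g$n_nodes), exact$support),
                      nbins = length(exact$support)) / length(s)
      expect_lt(total_variation(emp, exact$p), 0.02)
    }
  })
})

test_that("complete-graph dynamics sample the exact mean-field pmf", {
  g <- er_connectome(10, 1, seed = 1)
  for (lambda in c(1, 3, 5)) {  # n = 10: critical coupling is 5
    cfg <- sim_config(seed = 300 + lambda, lam0 = lambda, n_steps = 20000,
                      flips_per_step = 20, burn_in = 500)
    s <- metropolis_run(g, cfg)
    d <- synchrony_pmf(10, lambda)
    emp <- tabulate(match(round(s * 10), d$n), nbins = length(d$n)) / length(s)
    expect_lt(total_variation(emp, d$prob), 0.03)
  }
})

test_that("synchrony turns bimodal above the critical coupling", {
  g <- er_connectome(64, 0.4, seed = 13)
  kurt_ratio <- function(lam0) {
    cfg <- sim_config(seed = 77, lam0 = lam0, n_steps = 2000,
                      flips_per_step = 640, burn_in = 200)
    mom <- empirical_moments(metropolis_run(g, cfg))
    mom$m4 / mom$m2^2
  }
  # effective coupling lam0 * 0.4: deep subcritical at 16, supercritical at 96
  expect_gt(kurt_ratio(40), 2)   # Gaussian-like disorder: ratio near 3
  expect_lt(kurt_ratio(240), 2)  # two-peak order: ratio near 1
})

test_that("edge removal bookkeeping: counts, truncation, degenerate protocols", {
  g <- er_connectome(20, 0.5, seed = 2)
  cfg <- sim_config(seed = 2, lam0 = 10, n_steps = 100, flips_per_step = 40,
                    removal_batch = 5, removal_rounds = 6)
  tr <- edge_removal_experiment(g, cfg)
  rec <- tidy(tr)
  expect_equal(rec$n_edges, nrow(g$edges) - rec$round * 5)
  expect_equal(rec$avg_degree, 2 * rec$n_edges / 20)

  # zero rounds: a single record and no trend statistic
  tr0 <- edge_removal_experiment(g, sim_config(seed = 3, lam0 = 10,
                                               n_steps = 50,
                                               flips_per_step = 20,
                                               removal_rounds = 0))
  expect_equal(nrow(tidy(tr0)), 1L)
  expect_true(is.na(glance(tr0)$spearman_rho))

  # protocol larger than the graph warns and truncates
  small <- er_connectome(8, 0.5, seed = 4)
  warns <- capture_warnings(
    tr_tr <- edge_removal_experiment(
      small, sim_config(seed = 4, lam0 = 5, n_steps = 50, flips_per_step = 16,
                        removal_batch = 6, removal_rounds = 10))
  )
  expect_match(warns, "truncat", all = TRUE)
  expect_lt(nrow(tidy(tr_tr)), 11L)
})

test_that("identical seeds reproduce runs bit for bit", {
  g <- er_connectome(30, 0.3, seed = 6)
  cfg <- sim_config(seed = 8, lam0 = 20, n_steps = 200, flips_per_step = 60)
  expect_identical(metropolis_run(g, cfg), metropolis_run(g, cfg))
})
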