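test_that("the exact pmf matches brute-force enumeration of spin configurations", {
  withr::with_seed(31, {
    for (n_eff in c(2, 4, 7, 10, 12)) {
      lambda <- runif(1, 0, n_eff)
      d <- synchrony_pmf(n_eff, lambda)
      expect_lt(max(abs(d$prob - brute_force_pmf(n_eff, lambda))), 1e-12)
    }
  })
  # the worked case: n_eff = 4, lambda = 4, all five support probabilities
  d <- synchrony_pmf(4, 4)
  expect_equal(d$prob, brute_force_pmf(4, 4), tolerance = 1e-14)
})

test_that("the pmf normalizes, is symmetric, and reduces to the binomial at lambda = 0", {
  withr::with_seed(17, {
    for (i in 1:12) {
      n_eff <- sample(2:120, 1)
      lambda <- runif(1, -n_eff, 2 * n_eff)
      d <- synchrony_pmf(n_eff, lambda)
      expect_equal(sum(d$prob), 1, tolerance = 1e-12)
      expect_equal(d$prob, rev(d$prob), tolerance = 1e-12)
      expect_true(all(d$prob >= 0))
    }
  })
  d0 <- synchrony_pmf(30, 0)
  expect_equal(d0$prob, dbinom(0:30, 30, 0.5), tolerance = 1e-12)
  expect_error(synchrony_pmf(-3, 1), "n_eff")
})

test_that("model moments are exact at lambda = 0, saturate when ordered, and grow with lambda", {
  for (n_eff in c(10, 40, 64)) {
    expect_equal(meanfield_moments(n_eff, 0)$m2, 1 / n_eff, tolerance = 1e-12)
  }
  sat <- meanfield_moments(40, 400)
  expect_gt(sat$m2, 0.999)
  expect_gt(sat$m4, 0.999)
  m2s <- vapply(seq(0, 40, by = 2), function(l) meanfield_moments(40, l)$m2,
                numeric(1))
  expect_true(all(diff(m2s) > 0))
})

test_that("the critical coupling is half the effective region count", {
  expect_equal(critical_lambda(40), 20)
  expect_equal(critical_lambda(64), 32)  # 34.4 is supercritical
  expect_equal(critical_lambda(80) / critical_lambda(40), 2)
})

test_that("coupling fit inverts the model moments and flags nonphysical fits", {
  expect_equal(fit_lambda(1 / 40, 40)$lambda, 0)
  # round trips across the physical range
  for (lambda in c(0.5, 5, 25, 40, 70)) {
    m2 <- meanfield_moments(40, lambda)$m2
    f <- fit_lambda(m2, 40)
    expect_false(f$excluded)
    expect_equal(f$lambda, lambda, tolerance = 1e-6)
  }
  # sub-binomial variance needs a negative coupling: excluded, root kept
  f <- fit_lambda(0.5 / 40, 40)
  expect_true(f$excluded)
  expect_lt(f$lambda, 0)
  expect_error(fit_lambda(1.5, 40), "\\[0, 1\\]")
})

test_that("threshold calibration reproduces the quartic critical scaling", {
  # half-mass point of exp(-n_eff s^4 / 12) on [0, 1], by independent quadrature
  oracle <- function(n_eff) {
    tot <- integrate(function(s) exp(-n_eff * s^4 / 12), 0, 1)$value
    uniroot(function(x) {
      integrate(function(s) exp(-n_eff * s^4 / 12), 0, x)$value - tot / 2
    }, c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  }
  for (n_eff in c(20, 30, 40, 64, 100)) {
    expect_equal(calibrate_s_star(n_eff), oracle(n_eff), tolerance = 1e-7)
  }
  # s* follows the n_eff^(-1/4) law of the quartic critical density
  ratio <- vapply(seq(20, 100, by = 10),
                  function(n) calibrate_s_star(n) * n^0.25, numeric(1))
  expect_true(all(ratio > 0.82 & ratio < 0.86))
})

test_that("model Pseg conventions: calibration consistency, binomial oracle, limits", {
  # at the critical coupling the calibrated threshold encloses half the mass
  for (n_eff in c(30, 40, 64)) {
    m <- meanfield_model(n_eff, critical_lambda(n_eff))
    expect_equal(pseg_model(m, calibrate_s_star(n_eff))$pseg, 0.5,
                 tolerance = 1e-6)
  }
  # the grid method is the strict parity-grid sum: binomial oracle at lambda=0
  m0 <- meanfield_model(40, 0)
  # |n| < 40 * 0.33 = 13.2 keeps even |n| <= 12, i.e. 14 <= k <= 26 heads
  expect_equal(pseg_model(m0, 0.33, method = "grid")$pseg,
               sum(dbinom(14:26, 40, 0.5)), tolerance = 1e-12)
  # pseg + pint = 1 and monotone decay with coupling, both conventions
  s_star <- calibrate_s_star(40)
  for (method in c("landau", "grid")) {
    vals <- vapply(seq(0, 40, by = 4), function(l) {
      ps <- pseg_model(meanfield_model(40, l), s_star, method = method)
      expect_equal(ps$pseg + ps$pint, 1)
      ps$pseg
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # deep in the ordered phase all mass is integrated
  expect_lt(pseg_model(meanfield_model(40, 400), s_star, method = "grid")$pseg,
            1e-6)
})

test_that("the fourth-moment scan recovers a planted effective region count", {
  # subjects drawn from the exact model at n_eff = 40 with varying coupling;
  # moments computed analytically so the scan sees noiseless study data
  lambdas <- seq(5, 35, length.out = 15)
  moments <- purrr::map_dfr(lambdas, function(l) meanfield_moments(40, l))
  sc <- select_neff(moments, candidates = seq(20, 60, by = 5))
  expect_equal(sc$best, 40)
  expect_equal(tidy(sc)$n_eff, seq(20, 60, by = 5))
  expect_true(all(tidy(sc)$objective >= 0))
  expect_equal(glance(sc)$best_n_eff, 40)

  # a single candidate wins trivially
  expect_equal(select_neff(moments, candidates = 30)$best, 30)
  expect_error(select_neff(moments, candidates = integer(0)), "empty")
  # the cap drops candidates above the atlas size
  capped <- select_neff(moments, candidates = seq(20, 200, 5), n_max = 60)
  expect_lte(max(tidy(capped)$n_eff), 60)
})

test_that("scan objectives tolerate per-candidate exclusions", {
  # one subject with sub-binomial variance at large candidates only
  moments <- tibble::tibble(m2 = c(0.04, 0.10, 0.12), m4 = c(0.01, 0.03, 0.04))
  # at n_eff = 20, 1/n_eff = 0.05 > 0.04: first subject excluded there
  sc <- select_neff(moments, candidates = c(20, 30))
  expect_equal(tidy(sc)$n_used, c(2L, 3L))
})
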