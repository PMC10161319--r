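test_that("point-mass specs return base parameters; degenerate uniforms collapse", {
  m <- fixture_model()
  ps <- sample_parameters(point_specs(), m, seed = 7)
  expect_equal(ps$quantities,
               stats::setNames(m$items$quantity, m$items$id))
  expect_equal(ps$probabilities,
               stats::setNames(m$probs$value, m$probs$id))
  degen <- data.frame(parameter_ref = "q_entry", target = "quantity",
                      family = "uniform", p1 = 21.25, p2 = 21.25,
                      p3 = NA_real_, p4 = NA_real_)
  expect_equal(sample_parameters(degen, m, seed = 1)$quantities[["q_entry"]],
               21.25)
})

test_that("invalid distribution parameterisations are rejected", {
  m <- fixture_model()
  spec <- function(...) data.frame(..., p3 = NA_real_, p4 = NA_real_)
  expect_error(validate_dist_specs(
    spec(parameter_ref = "p_paper", target = "probability",
         family = "beta", p1 = -1, p2 = 5), m), "alpha")
  expect_error(validate_dist_specs(
    spec(parameter_ref = "p_paper", target = "probability",
         family = "gamma", p1 = 2, p2 = 2), m), "0,1")
  expect_error(validate_dist_specs(
    spec(parameter_ref = "p_paper", target = "probability",
         family = "uniform", p1 = 0.5, p2 = 1.5), m), "domain")
  expect_error(validate_dist_specs(
    spec(parameter_ref = "nope", target = "quantity",
         family = "point", p1 = 1, p2 = NA_real_), m), "nope")
})

test_that("PSA with point masses reproduces every deterministic cell; seeds reproduce bits", {
  m <- fixture_model()
  pt <- point_specs()
  for (se in names(m$settings)) for (st in names(m$strategies)) {
    r <- run_psa(m, st, se, pt, n_sims = 25, seed = 3)
    det <- evaluate_expected_cost(m, st, se)$total
    expect_equal(max(abs(r$samples - det)), 0, tolerance = 1e-9)
  }
  s1 <- run_psa(m, "TC", "trial", fixture_specs(), n_sims = 400, seed = 11)
  s2 <- run_psa(m, "TC", "trial", fixture_specs(), n_sims = 400, seed = 11)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$mean, s2$mean)
  s3 <- run_psa(m, "TC", "trial", fixture_specs(), n_sims = 400, seed = 12)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("PSA mean of a linear model sits within Monte Carlo error of the analytic value", {
  m <- toy_model(p = 0.4, costs = c(100, 50))
  # uniform +/-10% around the first activity's direct cost
  specs <- data.frame(parameter_ref = "a1", target = "quantity",
                      family = "uniform", p1 = 90, p2 = 110,
                      p3 = NA_real_, p4 = NA_real_)
  r <- run_psa(m, "ALL", "base", specs, n_sims = 10000, seed = 5)
  analytic <- 0.4 * 100 + 0.6 * 50
  se <- stats::sd(r$samples) / sqrt(r$n_sims)
  expect_lt(abs(r$mean - analytic), 3 * se)
  # law of large numbers through the same machinery: uniform(0,1) cost
  m01 <- toy_model(p = 1, costs = c(0.5, 99))
  specs01 <- data.frame(parameter_ref = "a1", target = "quantity",
                        family = "uniform", p1 = 0, p2 = 1,
                        p3 = NA_real_, p4 = NA_real_)
  r01 <- run_psa(m01, "ALL", "base", specs01, n_sims = 10000, seed = 6)
  expect_lt(abs(r01$mean - 0.5), 0.01)
})

test_that("pseudo-CI is the empirical 2.5/97.5 centile with type-7 quantiles", {
  expect_equal(pseudo_ci(rep(4.2, 50)), c(4.2, 4.2))
  set.seed(100)
  z <- stats::rnorm(10000)
  ci <- pseudo_ci(z)
  expect_equal(ci[1], -1.96, tolerance = 0.1)
  expect_equal(ci[2], 1.96, tolerance = 0.1)
  # translation and positive-scale equivariance
  expect_equal(pseudo_ci(z + 7), ci + 7, tolerance = 1e-12)
  expect_equal(pseudo_ci(3 * z), 3 * ci, tolerance = 1e-12)
  expect_equal(ci, unname(stats::quantile(z, c(0.025, 0.975), type = 7)))
  expect_error(pseudo_ci(numeric(0)), "empty")
})

test_that("DSA reproduces base totals, responds linearly, and brackets the base", {
  m <- fixture_model()
  base <- evaluate_expected_cost(m, "TC", "trial")$total
  tab <- run_dsa(m, "TC", "trial",
                 list(list(id = "noop", overrides = numeric(0))))
  expect_equal(tab$total, c(base, base))
  expect_equal(attr(tab, "max_abs_deviation"), 0)
  # doubling the survey data-entry minutes raises the total by exactly the
  # probability-weighted time cost of the extra minutes
  tab2 <- run_dsa(m, "TC", "trial",
                  list(list(id = "double_entry",
                            overrides = c(q_entry = 42.5))))
  expect_equal(tab2$total[2] - base, 0.05 * time_cost(21.25, 35),
               tolerance = 1e-9)
  # informant sets straddling the mean bracket the base total
  lo <- list(id = "lo", overrides = c(q_entry = 21.25 * 0.8,
                                      letter_retrieve = 7.5 * 0.8))
  hi <- list(id = "hi", overrides = c(q_entry = 21.25 * 1.2,
                                      letter_retrieve = 7.5 * 1.2))
  tab3 <- run_dsa(m, "TC", "trial", list(lo, hi))
  expect_lt(tab3$total[2], base)
  expect_gt(tab3$total[3], base)
  expect_error(run_dsa(m, "TC", "trial",
                       list(list(id = "bad", overrides = c(zzz = 1)))),
               "zzz")
})

test_that("convergence checkpoints are a prefix-consistent view of one stream", {
  m <- fixture_model()
  tab <- convergence_check(m, "TC", "trial", point_specs(), seed = 2,
                           checkpoints = c(50, 100))
  expect_true(all(tab$converged))          # point masses converge at once
  expect_equal(tab$mean, rep(evaluate_expected_cost(m, "TC", "trial")$total, 2),
               tolerance = 1e-9)
  specs <- fixture_specs()
  tab2 <- convergence_check(m, "TC", "trial", specs, seed = 2,
                            checkpoints = c(200, 400, 800))
  full <- run_psa(m, "TC", "trial", specs, n_sims = 800, seed = 2)
  expect_equal(tab2$mean[3], full$mean, tolerance = 1e-12)
  expect_equal(tab2$mean[1], mean(full$samples[1:200]), tolerance = 1e-12)
  # running mean at n and 2n agree within 3 pooled standard errors
  pooled_se <- stats::sd(full$samples) * sqrt(1 / 400 + 1 / 800)
  expect_lt(abs(tab2$mean[3] - tab2$mean[2]), 3 * pooled_se)
  expect_error(convergence_check(m, "TC", "trial", specs,
                                 checkpoints = c(100, 50)), "ascending")
})
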