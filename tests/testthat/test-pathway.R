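test_that("the packaged fixture builds a validated model with no unused items", {
  m <- fixture_model()
  expect_s3_class(m, "pathway_model")
  expect_named(m$strategies, c("TC", "TC_VBD", "TC_VBD_SNP"))
  expect_named(m$settings, c("trial", "nhs"))
  expect_length(attr(m, "validation")$unused_items, 0)
  # strategies are nested in component inclusion
  comp <- lapply(m$strategies, `[[`, "components")
  expect_true(all(comp$TC %in% comp$TC_VBD))
  expect_true(all(comp$TC_VBD %in% comp$TC_VBD_SNP))
})

test_that("writing the fixture and rebuilding yields an identical model", {
  dir <- withr::local_tempdir()
  make_paper_fixture(dir)
  m2 <- build_model(dir)
  m1 <- fixture_model()
  for (se in names(m1$settings)) for (st in names(m1$strategies))
    expect_equal(evaluate_expected_cost(m2, st, se)$total,
                 evaluate_expected_cost(m1, st, se)$total,
                 tolerance = 1e-12)
  expect_equal(m2$items$quantity, m1$items$quantity)
  expect_equal(m2$probs$value, m1$probs$value)
})

test_that("structural defects are rejected with the offending id", {
  m <- fixture_model()
  bad_probs <- m$probs
  bad_probs$value[bad_probs$id == "p_paper"] <- 1.2
  expect_error(
    build_model(unit_costs = m$unit_costs, items = m$items,
                probabilities = bad_probs,
                structure = paper_pathway()),
    "p_paper")
  bad_items <- m$items
  bad_items$unit_cost_ref[1] <- "no_such_unit"
  expect_error(
    build_model(unit_costs = m$unit_costs, items = bad_items,
                probabilities = m$probs, structure = paper_pathway()),
    "no_such_unit")
  expect_error(evaluate_expected_cost(m, "TC_MAGIC", "trial"), "TC_MAGIC")
  expect_error(evaluate_expected_cost(m, "TC", "space"), "space")
})

test_that("degenerate trees evaluate correctly", {
  # chance branch probability 0: only the complement and unconditional
  # activities contribute
  m <- toy_model(p = 0, costs = c(10, 0), unconditional = c(1, 2))
  expect_equal(evaluate_expected_cost(m, "ALL", "base")$total, 3)
  # symmetric two-branch average
  m2 <- toy_model(p = 0.5, costs = c(10, 20))
  expect_equal(evaluate_expected_cost(m2, "ALL", "base")$total, 15)
  eo <- enumerate_outcomes(m2, "ALL", "base")
  expect_equal(sum(eo$probability), 1, tolerance = 1e-12)
  expect_equal(sum(eo$probability * eo$cost), 15, tolerance = 1e-12)
})

test_that("the high-risk consultation branch matches its hand-computed product", {
  # p(high) x p(attends) x (organise + pack + consultant consult)
  m <- fixture_model()
  br <- evaluate_expected_cost(m, "TC", "trial",
                               probabilities = c(p_mod_tc = 0))
  hand <- 0.0147 * 0.7429 * (time_cost(2.25, 35) + time_cost(17.5, 35) +
                               time_cost(30, 123))
  expect_equal(br$per_stage[["consultation"]], hand, tolerance = 1e-9)
  expect_equal(hand, 0.797, tolerance = 1e-3)
})

test_that("outcome enumeration matches the recursive evaluator on the fixture", {
  m <- fixture_model()
  for (se in names(m$settings)) for (st in names(m$strategies)) {
    eo <- enumerate_outcomes(m, st, se)
    ev <- evaluate_expected_cost(m, st, se)
    expect_equal(sum(eo$probability), 1, tolerance = 1e-9)
    expect_equal(sum(eo$probability * eo$cost), ev$total,
                 tolerance = 1e-9 * ev$total)
    # breakdown internal consistency
    expect_equal(sum(ev$per_stage), ev$total, tolerance = 1e-4)
  }
  # the questionnaire-only strategy enumerates survey mode, follow-up,
  # risk category and uptake combinations
  eo <- enumerate_outcomes(m, "TC", "trial")
  expect_gte(nrow(eo), 12)
})

test_that("adding components or trial implementation issues never lowers cost", {
  m <- fixture_model()
  for (se in names(m$settings)) {
    tot <- sapply(c("TC", "TC_VBD", "TC_VBD_SNP"), function(st)
      evaluate_expected_cost(m, st, se)$total)
    expect_true(all(diff(tot) > 0))
  }
  for (st in names(m$strategies))
    expect_gte(evaluate_expected_cost(m, st, "trial")$total,
               evaluate_expected_cost(m, st, "nhs")$total)
})

test_that("stage shares sum to 100, need a positive total, and are scale-free", {
  m <- fixture_model()
  br <- evaluate_expected_cost(m, "TC_VBD", "trial")
  sh <- stage_shares(br)
  expect_equal(sum(sh), 100, tolerance = 0.01)
  # homogeneity: scaling every unit cost by k scales the breakdown by k
  m2 <- m
  m2$unit_costs$value_gbp <- 3 * m2$unit_costs$value_gbp
  m2$items$printed_cost_gbp <- 3 * m2$items$printed_cost_gbp
  br2 <- evaluate_expected_cost(m2, "TC_VBD", "trial")
  expect_equal(br2$total, 3 * br$total, tolerance = 1e-9)
  expect_equal(stage_shares(br2), sh, tolerance = 1e-9)
  # single-activity model concentrates 100% in one stage
  m1 <- toy_model(p = 1, costs = c(5, 0))
  expect_equal(max(stage_shares(evaluate_expected_cost(m1, "ALL", "base"))),
               100, tolerance = 1e-9)
  zero <- toy_model(p = 1, costs = c(0, 0))
  expect_error(stage_shares(evaluate_expected_cost(zero, "ALL", "base")),
               "zero")
})

test_that("report writers emit readable CSV grids with provenance headers", {
  dir <- withr::local_tempdir()
  m <- fixture_model()
  f <- file.path(dir, "t3.csv")
  write_table3_report(m, f, provenance = c(seed = "1"))
  expect_identical(readLines(f, n = 1), "# seed: 1")
  grid <- utils::read.csv(f, comment.char = "#", check.names = FALSE)
  expect_identical(grid$strategy, c("TC", "TC_VBD", "TC_VBD_SNP"))
  expect_equal(grid[grid$strategy == "TC", "trial"],
               round(evaluate_expected_cost(m, "TC", "trial")$total, 2))
  f2 <- file.path(dir, "stages.csv")
  write_stage_report(m, f2)
  st <- utils::read.csv(f2, comment.char = "#")
  expect_setequal(unique(st$stage), PATHWAY_STAGES)
})
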