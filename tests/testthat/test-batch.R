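test_that("chip count follows slot occupancy including the control sample", {
  s <- fixture_schedule()
  expect_identical(chips_required(47, s), 1)   # 47 + 1 control = 48 slots
  expect_identical(chips_required(48, s), 2)   # 49 slots forces a 2nd chip
  expect_identical(chips_required(95, s), 2)   # optimum fills both chips
  expect_error(chips_required(0, s), "batch_size")
})

test_that("staff-time model hits both published anchors", {
  s <- fixture_schedule()
  expect_equal(staff_minutes(1, s), 2165, tolerance = 1e-9)
  expect_equal(staff_minutes(95, s) / 96, 38.39, tolerance = 1e-9)
  # the calibration really is the solution of the 2x2 linear system
  ab <- solve_staff_anchors(2165, 38.39, 96, 2)
  expect_equal(unname(ab["fixed"] + ab["variable"] * 2), 2165)
  expect_equal(unname(ab["fixed"] + ab["variable"] * 96), 38.39 * 96)
  expect_equal(staff_cost(1, s), time_cost(2165, 41))
})

test_that("consumables are bought in whole boxes and cost steps upward", {
  one_box <- batch_schedule(
    chip_capacity = 48, chip_cost = 0, controls_per_batch = 0,
    max_batch = 95, staff_fixed_minutes = 0, staff_minutes_per_slot = 0,
    staff_rate = 0,
    consumables = data.frame(name = "x", box_cost = 10, box_size = 100,
                             usage = 1, basis = "per_sample"))
  expect_equal(consumable_cost(1, one_box), 10)    # a whole box for 1 sample
  expect_equal(consumable_cost(100, one_box), 10)
  expect_equal(consumable_cost(101, one_box), 20)
  s <- fixture_schedule()
  sweep <- consumable_cost(1:95, s)
  expect_true(all(diff(sweep) >= 0))
  # calibrated full-batch chips + consumables share matches the published
  # per-sample aggregate
  share <- (chips_required(95, s) * s$chip_cost + consumable_cost(95, s)) / 95
  expect_equal(share, 51.73, tolerance = 0.005)
})

test_that("per-batch consumables count controls once per batch, not per sample", {
  s <- batch_schedule(
    chip_capacity = 48, chip_cost = 0, controls_per_batch = 1,
    max_batch = 95, staff_fixed_minutes = 0, staff_minutes_per_slot = 0,
    staff_rate = 0,
    consumables = data.frame(name = c("per_s", "per_b"),
                             box_cost = c(1, 5), box_size = c(1, 1),
                             usage = c(1, 2),
                             basis = c("per_sample", "per_batch")))
  # 10 samples + control = 11 per-sample units, plus 2 per-batch units
  expect_equal(consumable_cost(10, s), 11 * 1 + 2 * 5)
})

test_that("the batch curve has the published shape", {
  s <- fixture_schedule()
  cv <- batch_curve(s)
  expect_identical(nrow(cv), 95L)
  ps <- cv$per_sample_cost
  expect_gt(ps[48], ps[47])                      # second chip kicks in
  expect_true(all(ps[48:71] > ps[47]))           # dearer until past 71
  expect_true(all(ps[72:95] < 100))              # below 100 from 72 on
  expect_identical(cv$batch_size[which.min(ps)], 95L)  # optimum at 95+1
  expect_true(all(diff(cv$batch_total) >= 0))
  expect_true(all(abs(cv$batch_total - ps * cv$batch_size) < 0.01))
  expect_error(batch_curve(s, 0, 95), "range")
  expect_error(per_sample_cost(96, s), "batch_size")
})

test_that("per-sample cost only rises at chip or box boundaries", {
  s <- fixture_schedule()
  cv <- batch_curve(s)
  ups <- which(diff(cv$per_sample_cost) > 0) + 1  # batch sizes that rose
  boundary <- vapply(cv$batch_size, function(b) {
    slots <- b + s$controls_per_batch
    chips_step <- chips_required(b, s) >
      chips_required(max(1, b - 1), s)
    box_step <- any(ceiling(slots / s$consumables$box_size) >
                      ceiling((slots - 1) / s$consumables$box_size))
    chips_step || box_step
  }, logical(1))
  expect_true(all(boundary[ups]))
})

test_that("with no consumables or staff the curve is pure chip amortisation", {
  bare <- batch_schedule(chip_capacity = 48, chip_cost = 1343.77,
                         controls_per_batch = 1, max_batch = 95,
                         staff_fixed_minutes = 0,
                         staff_minutes_per_slot = 0, staff_rate = 0)
  for (b in c(1, 20, 47, 48, 95))
    expect_equal(per_sample_cost(b, bare)$per_sample_cost,
                 chips_required(b, bare) * 1343.77 / b, tolerance = 1e-12)
})

test_that("strategy cost by batch size ties the curve to the pathway model", {
  m <- fixture_model()
  s <- fixture_schedule()
  tab <- strategy_cost_by_batch(m, s, "TC_VBD_SNP", "nhs",
                                batch_sizes = c(1, 95))
  br <- evaluate_expected_cost(m, "TC_VBD_SNP", "nhs")
  base <- br$total - br$per_stage[["snp"]]
  expect_equal(tab$strategy_cost,
               base + per_sample_cost(c(1, 95), s)$per_sample_cost,
               tolerance = 1e-9)
})
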