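test_that("discount factors leave cycle 1 undiscounted", {
  expect_equal(discount_factor(0.05, 1), 1)
  expect_equal(discount_factor(0.05, 4), 1.05^-3)
  expect_equal(discount_factor(0.05, 4), 0.863838, tolerance = 1e-6)
  expect_equal(discount_factor(0, 1:50), rep(1, 50))
  expect_error(discount_factor(0.05, 0), ">= 1")
})

test_that("currency conversion matches the published rate", {
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(24607), 17095, tolerance = 1e-4)
  expect_equal(convert_currency(43125), 29959, tolerance = 1e-4)
  expect_equal(convert_currency(28033), 19475, tolerance = 1e-4)
  expect_error(convert_currency(10, rate = 0), "positive")
})

test_that("INMB is the net-monetary-benefit identity", {
  expect_equal(compute_inmb(0, 0, 28033), 0)
  expect_equal(compute_inmb(-10, 0, 28033), 10)
  expect_equal(compute_inmb(-10, 0, 1), 10)
  expect_equal(compute_inmb(-7969.96, -26412 / 61394, 28033), -4090,
               tolerance = 1e-4)
  expect_error(compute_inmb(1, 1, 0), "positive")
})

test_that("accrual matches single-person closed forms", {
  # alive all cycle at utility 0.8, no discounting: 0.8 QALYs
  x <- flat_inputs(q = 0, utility = 0.8)
  x$econ$discount_rate <- 0
  co <- point_cohort(x, s = 1, state = 1, n = 1)
  acc <- accumulate(run_arm("usual_care", co, x, horizon = 1), x)
  expect_equal(acc$totals$qalys, 0.8)
  # dying within the cycle halves the accrual (trapezoid)
  x2 <- flat_inputs(q = 0.5, utility = 0.8)
  x2$econ$discount_rate <- 0
  acc2 <- accumulate(run_arm("usual_care", co, x2, horizon = 1), x2)
  expect_equal(acc2$totals$qalys, 0.8 * (1 + 0.5) / 2)
  # usual care charges exactly one primary procedure for a surviving person
  acc3 <- accumulate(run_arm("usual_care", co, x, horizon = 1), x)
  expect_equal(acc3$totals$cost, 24607)
  # exercise arm with zero uptake costs the program fee only, lifetime
  x4 <- flat_inputs(q = 0.01, utility = 0.8)
  x4$uptake$p_tkr_year1 <- 0
  x4$uptake$p_tkr_subsequent <- 0
  acc4 <- accumulate(run_arm("exercise", co, x4), x4)
  expect_equal(acc4$totals$cost, 1500)
  expect_equal(acc4$totals$primaries, 0)
})

test_that("discounting never increases nonnegative flows", {
  x <- base_inputs()
  res <- oa_run(x)
  x0 <- x
  x0$econ$discount_rate <- 0
  res0 <- oa_run(x0)
  for (arm in c("usual_care", "exercise")) {
    expect_lt(res$arms[[arm]]$totals$cost, res0$arms[[arm]]$totals$cost)
    expect_lt(res$arms[[arm]]$totals$qalys, res0$arms[[arm]]$totals$qalys)
  }
})

test_that("result object satisfies the INMB identity and per-person scaling", {
  x <- base_inputs()
  res <- oa_run(x)
  expect_equal(res$inmb,
               res$lambda * res$delta_qalys - res$delta_cost)
  expect_equal(res$per_person$inmb * res$total_n, res$inmb,
               tolerance = 1e-12)
  expect_equal(res$per_person$cost_exercise * res$total_n,
               res$arms$exercise$totals$cost, tolerance = 1e-9)
  # both increments negative here: ICER suppressed, INMB is the metric
  expect_lt(res$delta_cost, 0)
  expect_lt(res$delta_qalys, 0)
  expect_true(is.na(res$icer))
})

test_that("horizon sweep: truncated INMB and its sign crossover", {
  # null effect: QALY difference is zero at every horizon, so INMB(h) is the
  # pure cost saving and never changes sign
  r0 <- oa_run(null_inputs())
  hs0 <- horizon_sweep(r0)
  expect_true(all(hs0$inmb_pp > 0))
  expect_equal(attr(hs0, "crossover"), nrow(hs0))
  expect_equal(hs0$delta_qalys_pp, rep(0, nrow(hs0)), tolerance = 1e-9)
  # front-loaded surgical cost with a slowly accruing QALY advantage for
  # surgery: no later conversions or revisions, so the cost saving is all in
  # cycle 1 and the per-cycle QALY deficit makes INMB(h) strictly
  # nonincreasing (brute-force over every h)
  xm <- base_inputs()
  xm$uptake$p_tkr_year1 <- 1e-12
  xm$uptake$p_tkr_subsequent <- 1e-12
  xm$revision[] <- 0
  xm$mortality$intervals$ratio[] <- 1  # equal survival: pure utility deficit
  xm$mortality$ratio_k[] <- 1
  rm_ <- oa_run(xm)
  hsm <- horizon_sweep(rm_)
  expect_true(all(diff(hsm$inmb_pp) < 1e-9))
  # registry-like inputs: positive early INMB, negative lifetime INMB, a
  # well-defined last nonnegative horizon
  r1 <- oa_run(base_inputs())
  hs1 <- horizon_sweep(r1)
  expect_gt(hs1$inmb_pp[1], 0)
  cross <- attr(hs1, "crossover")
  expect_gt(cross, 0)
  expect_lt(cross, nrow(hs1))
  expect_gte(hs1$inmb_pp[cross], 0)
  expect_lt(hs1$inmb_pp[cross + 1], 0)
  # the lifetime endpoint of the sweep equals the full-run INMB
  expect_equal(hs1$inmb_pp[nrow(hs1)], r1$per_person$inmb, tolerance = 1e-9)
})
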