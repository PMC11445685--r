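test_that("cycle matrices are row-stochastic and match the engine update", {
  x <- base_inputs()
  co <- build_cohort(x)
  for (arm in c("usual_care", "exercise")) {
    tr <- run_arm(arm, co, x)
    for (s in c(1, 4, 8)) for (t in c(1, 2, 7)) {
      M <- build_cycle_matrix(s, arm, t, x$strata$start_age[s] + t - 1, x)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
      expect_lt(max(abs(tr[[s]]$occ[t, ] %*% M - tr[[s]]$occ[t + 1, ])),
                1e-9 * max(1, sum(tr[[s]]$occ[1, ])))
    }
  }
})

test_that("degenerate hazards behave as closed forms predict", {
  # no hazards, no uptake, past cycle 1: identity on alive states
  x <- flat_inputs(q = 0)
  x$uptake$p_tkr_year1 <- 0
  x$uptake$p_tkr_subsequent <- 0
  M <- build_cycle_matrix(1, "exercise", 2, 60, x)
  expect_equal(M[1:3, 1:3], diag(3), ignore_attr = TRUE)
  # q = 0.01, ratio 1, uptake 0: survival 0.99 stays, 0.01 to dead
  x2 <- flat_inputs(q = 0.01)
  x2$uptake$p_tkr_year1 <- 0
  x2$uptake$p_tkr_subsequent <- 0
  M2 <- build_cycle_matrix(1, "exercise", 2, 60, x2)
  n <- ncol(M2)
  expect_equal(unname(diag(M2)[1:3]), rep(0.99, 3))
  expect_equal(unname(M2[1:3, n]), rep(0.01, 3))
})

test_that("cumulative surgery uptake follows 1 - 0.74 * 0.92^(n-1)", {
  x <- flat_inputs(q = 0)  # keep published uptake 0.26 / 0.08
  co <- build_cohort(x)
  tr <- run_arm("exercise", co, x, horizon = 10)
  prim <- Reduce(`+`, lapply(tr, function(t) t$events$primaries))
  cum10 <- sum(prim) / co$total_n
  expect_equal(cum10, 1 - 0.74 * 0.92^9, tolerance = 1e-12)
  # and year by year
  cum <- cumsum(prim) / co$total_n
  expect_equal(cum, 1 - 0.74 * 0.92^(0:9), tolerance = 1e-12)
})

test_that("half-cycle correction is the trapezoid of the occupancy path", {
  occ <- matrix(c(1, 0.9, 0.8), ncol = 1)
  expect_equal(as.vector(half_cycle_occupancy(occ)), c(0.95, 0.85))
  const <- matrix(0.4, 5, 2)
  expect_equal(half_cycle_occupancy(const), matrix(0.4, 4, 2))
  # for a linearly declining cohort the trapezoid equals the exact integral
  f0 <- 1; fH <- 0.25; H <- 6
  lin <- matrix(seq(f0, fH, length.out = H + 1), ncol = 1)
  expect_equal(sum(half_cycle_occupancy(lin)), (f0 + fH) / 2 * H)
})

test_that("mass is conserved and event counts are monotone", {
  for (seed in c(1, 5)) {
    x <- generate_input_bundle(seed)
    co <- build_cohort(x)
    for (arm in c("usual_care", "exercise")) {
      tr <- run_arm(arm, co, x)
      for (t in tr) {
        n0 <- sum(t$occ[1, ])
        expect_lt(max(abs(rowSums(t$occ) - n0)), 1e-6 * max(n0, 1))
        expect_true(all(t$events >= 0))
      }
      prim_total <- sum(vapply(tr, function(t) sum(t$events$primaries),
                               numeric(1)))
      expect_lte(prim_total, co$total_n * (1 + 1e-9))
    }
  }
})

test_that("life-years match the geometric closed form under constant q", {
  q <- 0.02; s <- 1 - q
  x <- flat_inputs(q = q, utility = 1)
  x$econ$discount_rate <- 0
  co <- point_cohort(x, s = 1, state = 2, n = 1)
  tr <- run_arm("usual_care", co, x)
  acc <- accumulate(tr, x)
  H <- x$econ$max_age - x$strata$start_age[1] + 1
  # survival s^t until forced death at the age cap, trapezoid accrual
  ly_closed <- 0.5 + s * (1 - s^(H - 1)) / (1 - s)
  expect_equal(acc$totals$life_years, ly_closed, tolerance = 1e-9)
  expect_equal(acc$totals$qalys, ly_closed, tolerance = 1e-9)
})

test_that("usual care without hazards is a single post-operative transition", {
  x <- flat_inputs(q = 0)
  co <- build_cohort(x)
  tr <- run_arm("usual_care", co, x, horizon = 3)
  for (s in c(2, 5)) {
    base <- co$allocation[s, ]
    expected <- as.vector(base %*% x$transitions$P_tkr[s, , ])
    # after cycle 1 everyone is post-primary; pain mix is baseline x P
    occ2 <- tr[[s]]$occ[2, ]
    pain_mix <- occ2[4:6]
    expect_equal(unname(pain_mix), expected, tolerance = 1e-12)
    expect_equal(sum(occ2[1:3]), 0)
    # pain states persist down the tunnel
    expect_equal(unname(tr[[s]]$occ[4, 10:12]), expected, tolerance = 1e-12)
  }
})

test_that("truncating beyond the age cap logs and truncates", {
  x <- base_inputs()
  co <- build_cohort(x)
  expect_message(run_arm("exercise", co, x, horizon = 100), "truncated")
})
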