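test_that("one-way sweep: degenerate bounds and the closed-form program-cost span", {
  x <- flat_inputs(q = 0.02, utility = 0.8)
  x$uptake$p_tkr_year1 <- 0       # converter-free: program fee is the only
  x$uptake$p_tkr_subsequent <- 0  # cost difference, paid upfront
  params <- data.frame(name = "program_cost", low = 750, high = 3000)
  td <- one_way_dsa(x, params)
  expect_equal(td$inmb_low - td$inmb_high, 3000 - 750, tolerance = 1e-9)
  same <- data.frame(name = "program_cost", low = 1500, high = 1500)
  td0 <- one_way_dsa(x, same)
  expect_equal(td0$span, 0)
  expect_equal(td0$inmb_low, td0$inmb_base, tolerance = 1e-12)
})

test_that("tornado table covers all defaults, sorted by span, probabilities clipped", {
  x <- base_inputs()
  params <- default_dsa_params(x)
  td <- one_way_dsa(x, params)
  expect_setequal(td$name, params$name)
  expect_true(all(diff(td$span) <= 1e-12))
  # uncertainty in quality of life after the program dominates
  expect_equal(td$name[1], "incremental_utility_shift")
  expect_warning(set_model_param(x, "uptake_year1", 1.2), "clipped")
})

test_that("PSA is deterministic given the seed and unperturbed when frozen", {
  x <- base_inputs()
  p1 <- run_psa(x, n_sims = 8, seed = 42)
  p2 <- run_psa(x, n_sims = 8, seed = 42)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(x, n_sims = 8, seed = 43)
  expect_false(identical(p3$draws, p1$draws))
  # adding draws does not reshuffle earlier ones (keyed RNG streams)
  p4 <- run_psa(x, n_sims = 12, seed = 42)
  expect_identical(p4$draws[1:8, ], p1$draws)
  # frozen draws reproduce the base case exactly
  base <- oa_run(x)
  pf <- run_psa(x, n_sims = 3, seed = 42, perturb = FALSE)
  expect_equal(pf$draws$delta_cost, rep(base$per_person$delta_cost, 3))
  expect_equal(pf$draws$inmb, rep(base$per_person$inmb, 3))
})

test_that("PSA draws recover base-case input means (3-SE band)", {
  x <- base_inputs()
  n <- 10000
  # draw marginals via the fitted families rather than full model runs
  d_up <- fit_beta_from_ci(0.26, 0.14, 0.38)
  d_cost <- fit_gamma_from_mean_se(x$costs$primary_tkr,
                                   0.15 * x$costs$primary_tkr)
  d_pi <- dirichlet_from_counts(x$baseline$counts[3, ])
  set.seed(17)
  up1 <- oa_draw(d_up, n); cost <- oa_draw(d_cost, n); pi1 <- oa_draw(d_pi, n)
  expect_lt(abs(mean(up1) - 0.26), 3 * sd(up1) / sqrt(n))
  expect_lt(abs(mean(cost) - x$costs$primary_tkr), 3 * sd(cost) / sqrt(n))
  expect_true(all(abs(colMeans(pi1) - d_pi$mean) <
                    3 * apply(pi1, 2, sd) / sqrt(n)))
  # and the end-to-end drawn inputs stay valid model inputs
  xi <- draw_psa_inputs(x, seed = 9, draw = 1)
  expect_silent(validate_inputs(xi))
})

test_that("CEAC equals brute-force counting and quadrants sum to one", {
  x <- base_inputs()
  psa <- run_psa(x, n_sims = 25, seed = 3)
  th <- seq(0, 2 * x$econ$wtp_threshold, length.out = 21)
  curve <- ceac(psa, th)
  brute <- vapply(th, function(l)
    sum(l * psa$draws$delta_qalys - psa$draws$delta_cost > 0) / nrow(psa$draws),
    numeric(1))
  expect_equal(curve$prob_cost_effective, brute)
  expect_equal(sum(psa$quadrant_fractions), 1)
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))
})

test_that("CEAC counting on constructed draws gives the exact fractions", {
  fake <- function(dc, dq) {
    psa <- structure(list(draws = data.frame(draw = seq_along(dc),
                                             delta_cost = dc,
                                             delta_qalys = dq,
                                             inmb = NA)),
                     class = "oa_psa")
    psa
  }
  th <- c(0, 1000, 28033, 1e6)
  # pure savings, no QALY change: cost-effective everywhere
  expect_equal(ceac(fake(rep(-10, 4), rep(0, 4)), th)$prob_cost_effective,
               rep(1, 4))
  expect_equal(ceac(fake(rep(10, 4), rep(0, 4)), th)$prob_cost_effective,
               rep(0, 4))
  expect_equal(ceac(fake(c(-10, 10), c(0, 0)), th)$prob_cost_effective,
               rep(0.5, 4))
  # all QALY-positive draws: acceptability is nondecreasing in the threshold
  set.seed(4)
  dq <- runif(50, 0.01, 0.5); dc <- rnorm(50, 0, 2000)
  p <- ceac(fake(dc, dq), seq(0, 5e4, length.out = 40))$prob_cost_effective
  expect_true(all(diff(p) >= 0))
})
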