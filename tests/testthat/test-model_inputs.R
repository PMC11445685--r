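test_that("Beta fit from a 95% CI moment-matches mean and variance", {
  d <- fit_beta_from_ci(0.26, 0.14, 0.38)
  expect_equal(d$family, "beta")
  expect_equal(d$params$alpha, 13.085, tolerance = 1e-3)
  expect_equal(d$params$beta, 37.243, tolerance = 1e-3)
  # independent oracle: numerically integrate the fitted density
  a <- d$params$alpha; b <- d$params$beta
  m <- integrate(function(x) x * dbeta(x, a, b), 0, 1)$value
  v <- integrate(function(x) (x - m)^2 * dbeta(x, a, b), 0, 1)$value
  expect_equal(m, 0.26, tolerance = 1e-6)
  expect_equal(v, ((0.38 - 0.14) / 3.92)^2, tolerance = 1e-6)

  d2 <- fit_beta_from_ci(0.08, 0.03, 0.21)
  a <- d2$params$alpha; b <- d2$params$beta
  m2 <- integrate(function(x) x * dbeta(x, a, b), 0, 1)$value
  expect_equal(m2, 0.08, tolerance = 1e-6)
  v2 <- integrate(function(x) (x - m2)^2 * dbeta(x, a, b), 0, 1)$value
  expect_equal(v2, ((0.21 - 0.03) / 3.92)^2, tolerance = 1e-6)

  expect_equal(fit_beta_from_ci(0.5, 0.5, 0.5)$family, "fixed")
  expect_error(fit_beta_from_ci(0.5, 0.6, 0.7), "bracket")
})

test_that("Gamma fit from mean and SE reproduces both moments", {
  d <- fit_gamma_from_mean_se(1500, 225)
  expect_equal(d$params$shape, (1500 / 225)^2)
  expect_equal(d$params$scale, 225^2 / 1500)
  expect_equal(d$params$shape * d$params$scale, 1500)
  d2 <- fit_gamma_from_mean_se(24607, 0.15 * 24607)
  expect_equal(d2$params$shape, (1 / 0.15)^2, tolerance = 1e-12)
  expect_equal(d2$mean, 24607)
  # se -> 0 degenerates to a point mass at the mean
  expect_equal(fit_gamma_from_mean_se(42, 0)$family, "fixed")
  d3 <- fit_gamma_from_mean_se(42, 1e-6)
  expect_gt(d3$params$shape, 1e12)
  expect_error(fit_gamma_from_mean_se(-1, 2), "positive")
})

test_that("Dirichlet from counts has the right mean, analytically and by MC", {
  expect_equal(dirichlet_from_counts(c(2, 1, 1))$mean, c(0.5, 0.25, 0.25))
  expect_equal(dirichlet_from_counts(c(10, 0, 0))$mean, c(1, 0, 0))
  expect_equal(dirichlet_from_counts(c(0, 0, 0) + c(1, 0, 0),
                                     smoothing = TRUE)$mean,
               c(2, 1, 1) / 4)
  expect_error(dirichlet_from_counts(c(0, 0, 0)), "positive")
  set.seed(99)
  d <- dirichlet_from_counts(c(100, 200, 100))
  x <- oa_draw(d, 10000)
  p <- c(0.25, 0.5, 0.25)
  se <- sqrt(p * (1 - p) / (400 + 1)) / sqrt(10000)
  expect_true(all(abs(colMeans(x) - p) < 3 * se))
  expect_equal(rowSums(x), rep(1, 10000), tolerance = 1e-12)
})

test_that("fitted distributions reproduce base-case means to 1e-6 relative", {
  x <- base_inputs()
  up <- x$uptake
  fits <- list(
    fit_beta_from_ci(up$p_tkr_year1, up$ci_year1[1], up$ci_year1[2]),
    fit_beta_from_ci(up$p_tkr_subsequent, up$ci_subsequent[1],
                     up$ci_subsequent[2]),
    fit_gamma_from_mean_se(x$costs$primary_tkr, 0.15 * x$costs$primary_tkr),
    fit_gamma_from_mean_se(x$costs$revision_tkr, 0.15 * x$costs$revision_tkr),
    fit_lognormal_ratio(0.75, 0.1),
    dirichlet_from_counts(x$baseline$counts[1, ]))
  base <- list(up$p_tkr_year1, up$p_tkr_subsequent, x$costs$primary_tkr,
               x$costs$revision_tkr, 0.75,
               x$baseline$counts[1, ] / sum(x$baseline$counts[1, ]))
  for (i in seq_along(fits))
    expect_equal(fits[[i]]$mean, unname(unlist(base[i])), tolerance = 1e-6,
                 ignore_attr = TRUE)
  # mean-preserving log-normal: Monte Carlo mean matches the ratio
  set.seed(7)
  expect_equal(mean(oa_draw(fits[[5]], 200000)), 0.75, tolerance = 3e-3)
})

test_that("bundle write/load round trip is lossless and validated", {
  x <- base_inputs()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_input_bundle(x, d1)
  y <- load_input_bundle(d1)
  write_input_bundle(y, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_equal(y$baseline$pi, x$baseline$pi)
  expect_equal(y$transitions$P_tkr, x$transitions$P_tkr)
  expect_equal(y$mortality$q, x$mortality$q)
  expect_equal(y$utilities$du, x$utilities$du)
  expect_equal(y$revision, x$revision)
})

test_that("validation rejects malformed bundles and names the offender", {
  x <- base_inputs()
  d <- withr::local_tempdir()
  write_input_bundle(x, d)

  # transition row summing to 0.98
  tr <- read.csv(file.path(d, "transitions_tkr.csv"))
  i <- which(tr$age_band == "55-64" & tr$sex == "female" &
               tr$from_state == "moderate" & tr$to_state == "no_mild")[1]
  tr$probability[i] <- tr$probability[i] - 0.02
  write.csv(tr, file.path(d, "transitions_tkr.csv"), row.names = FALSE)
  expect_error(load_input_bundle(d), "transitions_tkr.*moderate")

  write_input_bundle(x, d)
  bp <- read.csv(file.path(d, "baseline_proportions.csv"))
  bp$proportion[5] <- bp$proportion[5] + 0.05
  write.csv(bp, file.path(d, "baseline_proportions.csv"), row.names = FALSE)
  expect_error(load_input_bundle(d), "baseline_proportions")

  write_input_bundle(x, d)
  file.remove(file.path(d, "mortality.csv"))
  expect_error(load_input_bundle(d), "mortality.csv")

  # baseline proportions are stored exactly as given
  write_input_bundle(x, d)
  bp <- read.csv(file.path(d, "baseline_proportions.csv"))
  sel <- bp$age_band == "45-54" & bp$sex == "female"
  bp$proportion[sel] <- c(0.2, 0.5, 0.3)
  write.csv(bp, file.path(d, "baseline_proportions.csv"), row.names = FALSE)
  y <- load_input_bundle(d)
  expect_identical(unname(y$baseline$pi[1, ]), c(0.2, 0.5, 0.3))
})
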