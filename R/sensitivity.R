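#' Deterministic and probabilistic sensitivity analysis
#'
#' The one-way analysis reruns the model with each parameter at its lower and
#' upper bound (95% CI bounds for uptake probabilities, +/-1.96 SE for costs
#' and disutilities, the stated range for the program cost, a log-scale
#' interval for the excess-mortality ratios, an additive shift for the
#' program's incremental utilities and the +/-A$500/year other-care
#' scenario), all else held at base case. The probabilistic analysis redraws
#' every stochastic input from its fitted family -- Dirichlet baseline and
#' transition rows (parameterized by their counts), Beta uptake
#' probabilities, Gamma costs, mean-preserving log-normal excess-mortality
#' ratios and Gamma revision disutilities (SE 25% of the mean) -- and reruns
#' both arms per draw.
#'
#' @name oacea-sensitivity
NULL

#' Default one-way sensitivity parameter table
#'
#' @param inputs An `oa_inputs` object.
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
default_dsa_params <- function(inputs) {
  cs <- inputs$costs
  up <- inputs$uptake
  ut <- inputs$utilities
  sef <- cs$surgical_cost_se_frac
  dsef <- ut$revision_disutility_se_frac
  ush <- 1.96 * ut$incremental_utility_se
  lsd <- 1.96 * inputs$lognormal_default_sdlog
  data.frame(
    name = c("uptake_year1", "uptake_subsequent",
             "primary_tkr_cost", "revision_tkr_cost", "program_cost",
             "excess_mortality_scale",
             "revision_disutility_event", "revision_disutility_chronic",
             "incremental_utility_shift", "other_annual_cost_delta"),
    low = c(up$ci_year1[1], up$ci_subsequent[1],
            cs$primary_tkr * (1 - 1.96 * sef),
            cs$revision_tkr * (1 - 1.96 * sef),
            cs$program_cost_range[1],
            exp(-lsd),
            ut$revision_disutility_event * (1 - 1.96 * dsef),
            ut$revision_disutility_chronic * (1 - 1.96 * dsef),
            -ush, cs$other_cost_delta_range[1]),
    high = c(up$ci_year1[2], up$ci_subsequent[2],
             cs$primary_tkr * (1 + 1.96 * sef),
             cs$revision_tkr * (1 + 1.96 * sef),
             cs$program_cost_range[2],
             exp(lsd),
             ut$revision_disutility_event * (1 + 1.96 * dsef),
             ut$revision_disutility_chronic * (1 + 1.96 * dsef),
             ush, cs$other_cost_delta_range[2]),
    stringsAsFactors = FALSE)
}

clip_prob <- function(p, what) {
  if (p < 0 || p > 1) {
    warning(what, " = ", p, " outside [0, 1]; clipped")
    p <- min(1 - 1e-12, max(1e-12, p))
  }
  p
}

#' Set one model parameter by name
#'
#' Used by the one-way sensitivity analysis; bounds that would produce an
#' invalid probability are clipped with a warning.
#'
#' @param inputs An `oa_inputs` object.
#' @param name Parameter name as in [default_dsa_params()].
#' @param value New value.
#' @return Modified `oa_inputs`.
#' @export
set_model_param <- function(inputs, name, value) {
  x <- inputs
  switch(name,
    uptake_year1 = {
      x$uptake$p_tkr_year1 <- clip_prob(value, name)
      x$uptake$ci_year1 <- range(x$uptake$ci_year1, x$uptake$p_tkr_year1)
    },
    uptake_subsequent = {
      x$uptake$p_tkr_subsequent <- clip_prob(value, name)
      x$uptake$ci_subsequent <- range(x$uptake$ci_subsequent,
                                      x$uptake$p_tkr_subsequent)
    },
    primary_tkr_cost = x$costs$primary_tkr <- value,
    revision_tkr_cost = x$costs$revision_tkr <- value,
    program_cost = x$costs$nonsurgical_program <- value,
    excess_mortality_scale = {
      x$mortality$intervals$ratio <- inputs$mortality$intervals$ratio * value
      x$mortality$ratio_k <- ratio_by_year(x$mortality$intervals, x$k_max)
    },
    revision_disutility_event = x$utilities$revision_disutility_event <- value,
    revision_disutility_chronic = x$utilities$revision_disutility_chronic <- value,
    incremental_utility_shift = x$utilities$du <- inputs$utilities$du + value,
    other_annual_cost_delta = x$costs$other_annual_cost_delta <- value,
    stop("unknown parameter: ", name)
  )
  x
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' @param inputs An `oa_inputs` object.
#' @param params Parameter table (`name`, `low`, `high`); defaults to
#'   [default_dsa_params()].
#' @param cohort Optional cohort.
#' @param lambda Threshold; defaults to the bundle's.
#' @return Data frame sorted by descending span, with the per-person INMB at
#'   each bound and at base case.
#' @export
one_way_dsa <- function(inputs, params = default_dsa_params(inputs),
                        cohort = NULL, lambda = NULL) {
  cohort <- cohort %||% build_cohort(inputs)
  lambda <- lambda %||% inputs$econ$wtp_threshold
  base <- oa_run(inputs, cohort, lambda)$per_person$inmb
  run_at <- function(name, value) {
    xi <- set_model_param(inputs, name, value)
    # baseline proportions are untouched by these parameters, reuse cohort
    oa_run(xi, cohort, lambda)$per_person$inmb
  }
  lo <- mapply(run_at, params$name, params$low)
  hi <- mapply(run_at, params$name, params$high)
  out <- data.frame(name = params$name, low = params$low, high = params$high,
                    inmb_low = lo, inmb_high = hi, inmb_base = base,
                    span = abs(hi - lo), stringsAsFactors = FALSE)
  out[order(-out$span), , drop = FALSE]
}

# deterministic sub-seed per (seed, draw, parameter path); one stream per
# drawn quantity so adding parameters does not reshuffle existing draws
hash_seed <- function(seed, draw, path) {
  h <- 0
  for (ch in utf8ToInt(path)) h <- (h * 31 + ch) %% 2147480009
  as.integer((seed %% 2027 * 1000003 + draw * 7919 + h) %% 2147483647)
}

draw_dirichlet_counts <- function(counts, smoothing) {
  d <- dirichlet_from_counts(counts, smoothing)
  for (try in seq_len(100)) {
    x <- as.vector(oa_draw(d, 1))
    if (all(is.finite(x)) && sum(x) > 0) return(x / sum(x))
  }
  stop("Dirichlet draw failed after 100 retries")
}

#' Draw one probabilistic-sensitivity-analysis input set
#'
#' @param inputs Base-case `oa_inputs`.
#' @param seed PSA seed.
#' @param draw Draw index (1-based).
#' @return A perturbed `oa_inputs`.
#' @export
draw_psa_inputs <- function(inputs, seed, draw) {
  x <- inputs
  sm <- inputs$dirichlet_smoothing
  ids <- inputs$strata$id
  for (s in seq_len(8)) {
    set.seed(hash_seed(seed, draw, paste0("baseline/", ids[s])))
    x$baseline$pi[s, ] <- draw_dirichlet_counts(inputs$baseline$counts[s, ], sm)
    for (j in 1:3) {
      set.seed(hash_seed(seed, draw, paste0("trans_tkr/", ids[s], "/", j)))
      x$transitions$P_tkr[s, j, ] <-
        draw_dirichlet_counts(inputs$transitions$counts_tkr[s, j, ], sm)
      set.seed(hash_seed(seed, draw, paste0("trans_ex/", ids[s], "/", j)))
      x$transitions$P_ex[s, j, ] <-
        draw_dirichlet_counts(inputs$transitions$counts_ex[s, j, ], sm)
    }
  }
  up <- inputs$uptake
  set.seed(hash_seed(seed, draw, "uptake/year1"))
  x$uptake$p_tkr_year1 <- oa_draw(
    fit_beta_from_ci(up$p_tkr_year1, up$ci_year1[1], up$ci_year1[2]), 1)
  x$uptake$ci_year1 <- range(up$ci_year1, x$uptake$p_tkr_year1)
  set.seed(hash_seed(seed, draw, "uptake/subsequent"))
  x$uptake$p_tkr_subsequent <- oa_draw(
    fit_beta_from_ci(up$p_tkr_subsequent, up$ci_subsequent[1],
                     up$ci_subsequent[2]), 1)
  x$uptake$ci_subsequent <- range(up$ci_subsequent, x$uptake$p_tkr_subsequent)

  cs <- inputs$costs
  sef <- cs$surgical_cost_se_frac
  # the Gamma draw is on the weighted mean; the public/private components
  # move by the same relative factor so the case-mix weighting stays coherent
  set.seed(hash_seed(seed, draw, "cost/primary"))
  x$costs$primary_tkr <- oa_draw(
    fit_gamma_from_mean_se(cs$primary_tkr, sef * cs$primary_tkr), 1)
  fac <- x$costs$primary_tkr / cs$primary_tkr
  x$costs$primary_tkr_public <- cs$primary_tkr_public * fac
  x$costs$primary_tkr_private <- cs$primary_tkr_private * fac
  set.seed(hash_seed(seed, draw, "cost/revision"))
  x$costs$revision_tkr <- oa_draw(
    fit_gamma_from_mean_se(cs$revision_tkr, sef * cs$revision_tkr), 1)
  fac <- x$costs$revision_tkr / cs$revision_tkr
  x$costs$revision_tkr_public <- cs$revision_tkr_public * fac
  x$costs$revision_tkr_private <- cs$revision_tkr_private * fac
  set.seed(hash_seed(seed, draw, "cost/program"))
  prog_se <- diff(range(cs$program_cost_range)) / 3.92
  x$costs$nonsurgical_program <- oa_draw(
    fit_gamma_from_mean_se(cs$nonsurgical_program, prog_se), 1)

  em <- inputs$mortality$intervals
  for (i in seq_len(nrow(em))) {
    if (em$sdlog[i] <= 0) next
    set.seed(hash_seed(seed, draw, paste0("excess/", em$years_from[i])))
    x$mortality$intervals$ratio[i] <- oa_draw(
      fit_lognormal_ratio(em$ratio[i], em$sdlog[i]), 1)
  }
  x$mortality$ratio_k <- ratio_by_year(x$mortality$intervals, x$k_max)

  ut <- inputs$utilities
  dsef <- ut$revision_disutility_se_frac
  if (ut$revision_disutility_event > 0) {
    set.seed(hash_seed(seed, draw, "disutil/event"))
    x$utilities$revision_disutility_event <- oa_draw(
      fit_gamma_from_mean_se(ut$revision_disutility_event,
                             dsef * ut$revision_disutility_event), 1)
  }
  if (ut$revision_disutility_chronic > 0) {
    set.seed(hash_seed(seed, draw, "disutil/chronic"))
    x$utilities$revision_disutility_chronic <- oa_draw(
      fit_gamma_from_mean_se(ut$revision_disutility_chronic,
                             dsef * ut$revision_disutility_chronic), 1)
  }
  x
}

#' Probabilistic sensitivity analysis
#'
#' @param inputs Base-case `oa_inputs`.
#' @param n_sims Number of Monte Carlo draws (1000 in the base analysis).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param lambda Threshold; defaults to the bundle's.
#' @param thresholds Threshold grid for the acceptability curve; defaults to
#'   0 to 2 lambda in 101 steps.
#' @param perturb If `FALSE`, inputs are frozen at base case and every draw
#'   reproduces the base-case result exactly (plumbing check).
#' @return An `oa_psa`: per-draw per-person `(delta_cost, delta_qalys, inmb)`
#'   triplets, the mean INMB with its percentile 95% uncertainty interval,
#'   cost-effectiveness-plane quadrant fractions and the acceptability curve.
#' @export
run_psa <- function(inputs, n_sims = 1000, seed = 42, lambda = NULL,
                    thresholds = NULL, perturb = TRUE) {
  stopifnot(inherits(inputs, "oa_inputs"), n_sims >= 1)
  lambda <- lambda %||% inputs$econ$wtp_threshold
  thresholds <- thresholds %||% seq(0, 2 * lambda, length.out = 101)
  dc <- dq <- numeric(n_sims)
  for (d in seq_len(n_sims)) {
    xi <- if (perturb) draw_psa_inputs(inputs, seed, d) else inputs
    res <- oa_run(xi, lambda = lambda)
    dc[d] <- res$per_person$delta_cost
    dq[d] <- res$per_person$delta_qalys
  }
  inmb <- compute_inmb(dc, dq, lambda)
  draws <- data.frame(draw = seq_len(n_sims), delta_cost = dc,
                      delta_qalys = dq, inmb = inmb)
  quad <- c(ne = mean(dq > 0 & dc > 0), se = mean(dq > 0 & dc <= 0),
            sw = mean(dq <= 0 & dc <= 0), nw = mean(dq <= 0 & dc > 0))
  psa <- structure(list(
    draws = draws, seed = seed, lambda = lambda, n_sims = n_sims,
    mean_inmb = mean(inmb),
    ci_inmb = unname(stats::quantile(inmb, c(0.025, 0.975), type = 7)),
    quadrant_fractions = quad,
    prob_cost_effective = mean(inmb > 0)
  ), class = "oa_psa")
  psa$ceac <- ceac(psa, thresholds)
  psa
}

#' @export
print.oa_psa <- function(x, ...) {
  cat(sprintf("<oa_psa> %d draws (seed %d)\n", x$n_sims, x$seed))
  cat(sprintf("  mean INMB A$%.0f per person (95%% UI %.0f to %.0f)\n",
              x$mean_inmb, x$ci_inmb[1], x$ci_inmb[2]))
  cat(sprintf("  cost-effective at lambda A$%d/QALY in %.1f%% of draws\n",
              round(x$lambda), 100 * x$prob_cost_effective))
  cat(sprintf("  CE-plane quadrants: NE %.1f%%, SE %.1f%%, SW %.1f%%, NW %.1f%%\n",
              100 * x$quadrant_fractions["ne"], 100 * x$quadrant_fractions["se"],
              100 * x$quadrant_fractions["sw"], 100 * x$quadrant_fractions["nw"]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold, the fraction of PSA draws with positive net monetary
#' benefit.
#'
#' @param psa An `oa_psa` object.
#' @param thresholds Numeric grid of willingness-to-pay values.
#' @return Data frame `threshold`, `prob_cost_effective`.
#' @export
ceac <- function(psa, thresholds) {
  stopifnot(inherits(psa, "oa_psa"), length(thresholds) >= 1)
  dc <- psa$draws$delta_cost
  dq <- psa$draws$delta_qalys
  p <- vapply(thresholds, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(threshold = thresholds, prob_cost_effective = p)
}
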