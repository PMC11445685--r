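#' Discounting, accrual and decision metrics
#'
#' Costs and QALYs are discounted at an annual rate with cycle-1 flows
#' undiscounted: the factor for cycle `t` is `(1 + rate)^-(t - 1)`. QALYs and
#' continuous costs accrue on half-cycle corrected occupancy; event costs
#' (procedures) and the one-off revision disutility apply to event counts in
#' the cycle they occur, undiscounted within the cycle.
#'
#' @name oacea-economics
NULL

#' Discount factor for an annual cycle
#'
#' @param rate Annual discount rate (fraction).
#' @param cycle Cycle number, 1-based; cycle 1 is undiscounted.
#' @return `(1 + rate)^-(cycle - 1)`.
#' @export
discount_factor <- function(rate, cycle) {
  if (any(cycle < 1)) stop("cycle must be >= 1")
  (1 + rate)^(-(cycle - 1))
}

#' Convert Australian dollars to US dollars
#'
#' @param amount_aud Amount in A$.
#' @param rate USD per A$ (default 0.6947, the 2022 purchasing-power rate
#'   used throughout).
#' @return Amount in USD; rounding is left to render time.
#' @export
convert_currency <- function(amount_aud, rate = 0.6947) {
  if (rate <= 0) stop("currency rate must be positive")
  amount_aud * rate
}

#' Incremental net monetary benefit
#'
#' `INMB = lambda * delta_qalys - delta_cost`; positive values favour the
#' education and exercise program.
#'
#' @param delta_cost Incremental cost (program minus usual care), A$.
#' @param delta_qalys Incremental QALYs.
#' @param lambda Willingness-to-pay threshold, A$ per QALY.
#' @return INMB in A$.
#' @export
compute_inmb <- function(delta_cost, delta_qalys, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  lambda * delta_qalys - delta_cost
}

# utility vector over the expanded state space for one stratum/arm.
# Pre-surgical utilities are cycle-dependent: baseline values at the start of
# cycle 1; from cycle 2 the exercise arm carries the mass-weighted mean of
# baseline utility plus the transition-specific incremental utility, because
# the program's pain transition is applied once in cycle 1.
utility_vectors <- function(inputs, s, arm, n0_pain) {
  K <- inputs$k_max
  ut <- inputs$utilities
  u_b <- ut$u_base[s, ]
  u_p <- ut$u_post[s, ]
  ubar <- u_b
  if (arm == "exercise") {
    denom <- as.vector(n0_pain %*% inputs$transitions$P_ex[s, , ])
    num <- vapply(1:3, function(j)
      sum(n0_pain * inputs$transitions$P_ex[s, , j] * (u_b + ut$du[, j])),
      numeric(1))
    ubar <- ifelse(denom > 0, num / pmax(denom, .Machine$double.xmin), 0)
  }
  u_post_block <- rep(u_p, K)
  u_rev_block <- rep(u_p - ut$revision_disutility_chronic, K)
  list(first = c(u_b, u_post_block, u_rev_block, 0),
       later = c(ubar, u_post_block, u_rev_block, 0))
}

#' Accumulate discounted costs and QALYs from trajectories
#'
#' @param trajectories Output of [run_arm()] for one arm.
#' @param inputs An `oa_inputs` object.
#' @return A list with `totals` (`cost`, `qalys`, `life_years`, `primaries`,
#'   `revisions`, `n_init`) and `streams`, a per-cycle data frame of
#'   discounted flows aggregated over strata (used by [horizon_sweep()]).
#' @export
accumulate <- function(trajectories, inputs) {
  arm <- attr(trajectories, "arm")
  r <- inputs$econ$discount_rate
  cs <- inputs$costs
  ev_dis <- inputs$utilities$revision_disutility_event
  Hmax <- max(vapply(trajectories, function(tr) tr$horizon, integer(1)))
  agg <- matrix(0, Hmax, 5,
                dimnames = list(NULL, c("cost", "qaly", "ly",
                                        "primaries", "revisions")))
  n_init <- 0
  for (s in seq_along(trajectories)) {
    tr <- trajectories[[s]]
    H <- tr$horizon
    if (sum(tr$occ[1, ]) == 0) next
    n_init <- n_init + sum(tr$occ[1, ])
    disc <- discount_factor(r, seq_len(H))
    uv <- utility_vectors(inputs, s, arm, tr$occ[1, 1:3])
    U <- c(drop(tr$occ[1, , drop = FALSE] %*% uv$first),
           as.vector(tr$occ[-1, , drop = FALSE] %*% uv$later))
    dead_i <- ncol(tr$occ)
    A <- rowSums(tr$occ[, -dead_i, drop = FALSE])
    qaly <- disc * ((U[seq_len(H)] + U[seq_len(H) + 1]) / 2 -
                      ev_dis * tr$events$revisions)
    ly <- disc * (A[seq_len(H)] + A[seq_len(H) + 1]) / 2
    cost <- disc * (tr$events$primaries * cs$primary_tkr +
                      tr$events$revisions * cs$revision_tkr)
    if (arm == "exercise")
      cost[1] <- cost[1] + cs$nonsurgical_program * sum(tr$occ[1, ])
    if (cs$other_annual_cost_delta != 0) {
      ny <- min(H, cs$other_cost_delta_years)
      eff_alive <- (A[seq_len(ny)] + A[seq_len(ny) + 1]) / 2
      cost[seq_len(ny)] <- cost[seq_len(ny)] +
        disc[seq_len(ny)] * cs$other_annual_cost_delta * eff_alive
    }
    agg[seq_len(H), "cost"] <- agg[seq_len(H), "cost"] + cost
    agg[seq_len(H), "qaly"] <- agg[seq_len(H), "qaly"] + qaly
    agg[seq_len(H), "ly"] <- agg[seq_len(H), "ly"] + ly
    agg[seq_len(H), "primaries"] <- agg[seq_len(H), "primaries"] +
      tr$events$primaries
    agg[seq_len(H), "revisions"] <- agg[seq_len(H), "revisions"] +
      tr$events$revisions
  }
  streams <- data.frame(cycle = seq_len(Hmax), agg)
  list(totals = list(cost = sum(agg[, "cost"]), qalys = sum(agg[, "qaly"]),
                     life_years = sum(agg[, "ly"]),
                     primaries = sum(agg[, "primaries"]),
                     revisions = sum(agg[, "revisions"]), n_init = n_init),
       streams = streams)
}

#' Run the full cost-utility comparison
#'
#' Runs both arms over the lifetime horizon, accrues discounted costs and
#' QALYs, and computes the incremental results. The ICER is reported as `NA`
#' (suppressed) when both increments are negative, in which case the INMB is
#' the decision metric.
#'
#' @param inputs An `oa_inputs` object.
#' @param cohort Optional `oa_cohort`; defaults to [build_cohort()] from the
#'   bundle.
#' @param lambda Willingness-to-pay threshold; defaults to the bundle's.
#' @param horizon Optional truncation in cycles.
#' @return An `oa_result` with per-arm totals and streams, incrementals,
#'   INMB, ICER, event summaries and per-person views.
#' @export
oa_run <- function(inputs, cohort = NULL, lambda = NULL, horizon = NULL) {
  stopifnot(inherits(inputs, "oa_inputs"))
  cohort <- cohort %||% build_cohort(inputs)
  lambda <- lambda %||% inputs$econ$wtp_threshold
  arms <- list()
  for (arm in c("exercise", "usual_care")) {
    tr <- run_arm(arm, cohort, inputs, horizon)
    arms[[arm]] <- accumulate(tr, inputs)
  }
  n <- cohort$total_n
  dc <- arms$exercise$totals$cost - arms$usual_care$totals$cost
  dq <- arms$exercise$totals$qalys - arms$usual_care$totals$qalys
  dly <- arms$exercise$totals$life_years - arms$usual_care$totals$life_years
  inmb_pp <- compute_inmb(dc / n, dq / n, lambda)
  icer <- if (dq < 0 && dc < 0) NA_real_ else dc / dq
  fewer_prim <- arms$usual_care$totals$primaries - arms$exercise$totals$primaries
  fewer_rev <- arms$usual_care$totals$revisions - arms$exercise$totals$revisions
  structure(list(
    total_n = n,
    arms = arms,
    lambda = lambda,
    currency_rate = inputs$econ$currency_rate,
    delta_cost = dc, delta_qalys = dq, delta_life_years = dly,
    inmb = compute_inmb(dc, dq, lambda), icer = icer,
    per_person = list(
      cost_exercise = arms$exercise$totals$cost / n,
      cost_usual_care = arms$usual_care$totals$cost / n,
      qalys_exercise = arms$exercise$totals$qalys / n,
      qalys_usual_care = arms$usual_care$totals$qalys / n,
      delta_cost = dc / n, delta_qalys = dq / n, inmb = inmb_pp),
    events = list(fewer_primaries = fewer_prim, fewer_revisions = fewer_rev,
                  fewer_total = fewer_prim + fewer_rev,
                  tkr_avoidance_frac = fewer_prim / n)
  ), class = "oa_result")
}

#' @export
print.oa_result <- function(x, ...) {
  usd <- function(a) convert_currency(a, x$currency_rate)
  f0 <- function(a) formatC(a, format = "d", big.mark = " ")
  cat("<oa_result> lifetime cost-utility, cohort n =", f0(round(x$total_n)), "\n")
  cat(sprintf("  cost:   program A$%s, usual care A$%s (delta A$%s / $%s)\n",
              f0(round(x$arms$exercise$totals$cost)),
              f0(round(x$arms$usual_care$totals$cost)),
              f0(round(x$delta_cost)), f0(round(usd(x$delta_cost)))))
  cat(sprintf("  QALYs:  program %s, usual care %s (delta %s)\n",
              f0(round(x$arms$exercise$totals$qalys)),
              f0(round(x$arms$usual_care$totals$qalys)),
              f0(round(x$delta_qalys))))
  cat(sprintf("  per person: delta cost A$%.0f, delta QALYs %.2f\n",
              x$per_person$delta_cost, x$per_person$delta_qalys))
  cat(sprintf("  INMB at lambda A$%s/QALY: A$%.0f per person ($%.0f)\n",
              f0(x$lambda), x$per_person$inmb, usd(x$per_person$inmb)))
  if (is.na(x$icer))
    cat("  ICER suppressed (both increments negative); INMB is the metric\n")
  else cat(sprintf("  ICER: A$%.0f per QALY\n", x$icer))
  cat(sprintf("  fewer procedures: %.0f primary + %.0f revision = %.0f (%.1f%% avoid surgery)\n",
              x$events$fewer_primaries, x$events$fewer_revisions,
              x$events$fewer_total, 100 * x$events$tkr_avoidance_frac))
  invisible(x)
}

#' INMB as a function of the truncation horizon
#'
#' Recomputes the per-person INMB from the discounted incremental streams
#' truncated at each horizon `h = 1..lifetime`. The `crossover` attribute
#' holds the largest `h` with `INMB(h) >= 0` (0 if none).
#'
#' @param result An `oa_result`.
#' @param lambda Threshold; defaults to the result's.
#' @return Data frame `h`, `delta_cost_pp`, `delta_qalys_pp`, `inmb_pp` with
#'   attribute `crossover`.
#' @export
horizon_sweep <- function(result, lambda = NULL) {
  stopifnot(inherits(result, "oa_result"))
  lambda <- lambda %||% result$lambda
  ex <- result$arms$exercise$streams
  uc <- result$arms$usual_care$streams
  H <- max(nrow(ex), nrow(uc))
  pad <- function(v, H) c(v, rep(0, H - length(v)))
  dc <- cumsum(pad(ex$cost, H) - pad(uc$cost, H)) / result$total_n
  dq <- cumsum(pad(ex$qaly, H) - pad(uc$qaly, H)) / result$total_n
  inmb <- compute_inmb(dc, dq, lambda)
  out <- data.frame(h = seq_len(H), delta_cost_pp = dc, delta_qalys_pp = dq,
                    inmb_pp = inmb)
  attr(out, "crossover") <- if (any(inmb >= 0)) max(which(inmb >= 0)) else 0L
  out
}
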