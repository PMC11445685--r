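#' Individual-level microsimulation oracle
#'
#' Simulates individuals through the identical event logic as the cohort
#' engine -- annual death with post-surgical excess mortality, program-to-
#' surgery conversion, one-time revision, the one-off exercise pain
#' transition, half-cycle utility accrual and event costs -- and returns
#' Monte Carlo means with standard errors. Because the cohort model is the
#' exact expectation of this process, per-arm per-person means must agree
#' within Monte Carlo error; the microsimulation serves as an independent
#' cross-check of the cohort engine.
#'
#' @param inputs An `oa_inputs` object.
#' @param n_individuals Number of simulated persons per arm.
#' @param seed Integer seed.
#' @param arms Arms to simulate.
#' @param cohort Optional `oa_cohort`; defaults to [build_cohort()].
#' @param horizon Optional truncation in cycles.
#' @return Data frame with one row per arm: mean and SE of per-person
#'   discounted cost, QALYs and life-years.
#' @export
microsim_oracle <- function(inputs, n_individuals, seed = 1,
                            arms = c("usual_care", "exercise"),
                            cohort = NULL, horizon = NULL) {
  stopifnot(inherits(inputs, "oa_inputs"), n_individuals >= 1)
  cohort <- cohort %||% build_cohort(inputs)
  if (is.null(cohort$allocation))
    stop("cohort has no baseline allocation")
  w <- cohort$allocation / cohort$total_n

  # deterministic integer allocation of persons to (stratum, state) cells:
  # floors plus largest-remainder top-up
  tgt <- w * n_individuals
  n_cell <- floor(tgt)
  rem <- n_individuals - sum(n_cell)
  if (rem > 0) {
    ord <- order(tgt - n_cell, decreasing = TRUE)
    n_cell[ord[seq_len(rem)]] <- n_cell[ord[seq_len(rem)]] + 1
  }

  out <- lapply(arms, function(arm) {
    set.seed(as.integer(seed) + match(arm, c("usual_care", "exercise")) * 1000003L)
    cost <- qaly <- ly <- numeric(0)
    for (s in seq_len(nrow(inputs$strata))) {
      ns <- sum(n_cell[s, ])
      if (ns == 0) next
      pain0 <- rep(1:3, times = n_cell[s, ])
      r <- microsim_stratum(inputs, s, arm, pain0, horizon)
      cost <- c(cost, r$cost); qaly <- c(qaly, r$qaly); ly <- c(ly, r$ly)
    }
    n <- length(cost)
    data.frame(arm = arm, n = n,
               mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
               mean_qalys = mean(qaly), se_qalys = stats::sd(qaly) / sqrt(n),
               mean_ly = mean(ly), se_ly = stats::sd(ly) / sqrt(n))
  })
  do.call(rbind, out)
}

# categorical draw per person given a 3x3 row-stochastic matrix and the
# per-person current state
sample_transition <- function(P, from) {
  to <- integer(length(from))
  for (j in 1:3) {
    idx <- which(from == j)
    if (length(idx) == 0) next
    cp <- cumsum(P[j, ])
    to[idx] <- findInterval(stats::runif(length(idx)), cp[1:2]) + 1L
  }
  to
}

microsim_stratum <- function(inputs, s, arm, pain0, horizon = NULL) {
  n <- length(pain0)
  K <- inputs$k_max
  start_age <- inputs$strata$start_age[s]
  max_age <- inputs$econ$max_age
  H <- max_age - start_age + 1L
  if (!is.null(horizon)) H <- min(H, as.integer(horizon))
  disc <- discount_factor(inputs$econ$discount_rate, seq_len(H))
  up <- arm_uptake(arm, inputs)
  qs <- q_for_ages(inputs, inputs$strata$sex[s], start_age + seq_len(H) - 1L)
  rk <- inputs$mortality$ratio_k
  Ptkr <- inputs$transitions$P_tkr[s, , ]
  Pex <- inputs$transitions$P_ex[s, , ]
  rev_p <- inputs$revision[s, ]
  ut <- inputs$utilities
  u_b <- ut$u_base[s, ]; u_p <- ut$u_post[s, ]
  cs <- inputs$costs

  pain <- pain0
  status <- integer(n)            # 0 pre, 1 post-primary, 2 post-revision, 3 dead
  k <- integer(n)                 # years since primary surgery
  util <- u_b[pain]
  cost <- qaly <- ly <- numeric(n)
  if (arm == "exercise") cost <- cost + cs$nonsurgical_program

  for (t in seq_len(H)) {
    age <- start_age + t - 1L
    alive <- status < 3L
    if (!any(alive)) break
    u_start <- ifelse(alive, util, 0)
    a_start <- as.numeric(alive)
    status0 <- status

    ratio <- rep(1, n)
    post <- alive & status0 > 0L
    ratio[post] <- rk[pmin(k[post], K)]
    pdie <- pmin(1, qs[t] * ratio)
    die <- alive & (stats::runif(n) < pdie)
    surv <- alive & !die

    u_cycle <- if (t == 1) up[1] else up[2]
    pre_idx <- which(surv & status0 == 0L)
    if (length(pre_idx) > 0) {
      conv <- pre_idx[stats::runif(length(pre_idx)) < u_cycle]
      if (length(conv) > 0) {
        newpain <- sample_transition(Ptkr, pain[conv])
        pain[conv] <- newpain
        status[conv] <- 1L
        k[conv] <- 1L
        util[conv] <- u_p[newpain]
        cost[conv] <- cost[conv] + disc[t] * cs$primary_tkr
      }
      noncon <- setdiff(pre_idx, conv)
      if (t == 1 && length(noncon) > 0) {
        old <- pain[noncon]
        newpain <- sample_transition(Pex, old)
        pain[noncon] <- newpain
        util[noncon] <- u_b[old] + ut$du[cbind(old, newpain)]
      }
    }

    prim_idx <- which(surv & status0 == 1L)
    if (length(prim_idx) > 0) {
      rp <- rev_p[pmin(k[prim_idx], K)]
      revd <- prim_idx[stats::runif(length(prim_idx)) < rp]
      if (length(revd) > 0) {
        status[revd] <- 2L
        util[revd] <- u_p[pain[revd]] - ut$revision_disutility_chronic
        cost[revd] <- cost[revd] + disc[t] * cs$revision_tkr
        qaly[revd] <- qaly[revd] - disc[t] * ut$revision_disutility_event
      }
    }
    adv <- surv & status0 > 0L
    k[adv] <- pmin(k[adv] + 1L, K)

    status[die] <- 3L
    if (age >= max_age) status[status < 3L] <- 3L

    dead_now <- status == 3L
    u_end <- ifelse(dead_now, 0, util)
    a_end <- as.numeric(!dead_now)
    qaly <- qaly + disc[t] * (u_start + u_end) / 2
    ly <- ly + disc[t] * (a_start + a_end) / 2
    if (cs$other_annual_cost_delta != 0 && t <= cs$other_cost_delta_years)
      cost <- cost + disc[t] * cs$other_annual_cost_delta * (a_start + a_end) / 2
  }
  list(cost = cost, qaly = qaly, ly = ly)
}
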