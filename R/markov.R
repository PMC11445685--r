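#' Annual-cycle semi-Markov cohort engine
#'
#' Both arms run through one engine over the expanded state space of
#' [expanded_states()]. Within each annual cycle the event order is fixed:
#' (1) death, with probability `q(age, sex)` times the years-since-surgery
#' excess-mortality ratio for post-surgical states (capped at 1);
#' (2) among surviving pre-surgical persons, conversion to surgery with the
#' year-1 uptake probability in cycle 1 and the subsequent-year probability
#' thereafter -- converters receive the post-operative pain transition and
#' enter the first post-primary tunnel state, and in cycle 1 non-converters
#' receive the exercise-program pain transition (applied once; pain is static
#' afterwards);
#' (3) among post-primary persons, revision with the year-specific revision
#' probability, else advance one tunnel year (held at `k_max`); revision is a
#' one-time event.
#' The usual-care arm is the same operator with both uptake probabilities set
#' to 1, so the whole surviving cohort undergoes surgery in cycle 1. Anyone
#' alive at the maximum age dies at the end of that cycle.
#'
#' @name oacea-engine
NULL

stratum_index <- function(inputs, stratum) {
  if (is.numeric(stratum)) return(as.integer(stratum))
  i <- match(stratum, inputs$strata$id)
  if (is.na(i)) stop("unknown stratum: ", stratum)
  i
}

arm_uptake <- function(arm, inputs) {
  if (arm == "usual_care") c(1, 1)
  else c(inputs$uptake$p_tkr_year1, inputs$uptake$p_tkr_subsequent)
}

q_for_ages <- function(inputs, sex, ages) {
  q <- inputs$mortality$q
  tab_ages <- as.integer(rownames(q))
  q[match(pmin(pmax(ages, min(tab_ages)), max(tab_ages)), tab_ages), sex]
}

#' One-cycle transition matrix over the expanded state space
#'
#' Builds the explicit row-stochastic operator applied by the engine in a
#' given cycle, mainly for verification: [run_arm()] uses an equivalent
#' vectorized update. Rows sum to 1 to within 1e-12.
#'
#' @param stratum Stratum id or index.
#' @param arm `"usual_care"` or `"exercise"`.
#' @param cycle Cycle number (1-based; cycle 1 uses the year-1 uptake and the
#'   one-off exercise pain transition).
#' @param attained_age Age at the start of the cycle.
#' @param inputs An `oa_inputs` object.
#' @return An `n x n` transition matrix over [expanded_states()].
#' @export
build_cycle_matrix <- function(stratum, arm, cycle, attained_age, inputs) {
  s <- stratum_index(inputs, stratum)
  K <- inputs$k_max
  nS <- n_expanded_states(K)
  dead <- idx_dead(K)
  M <- matrix(0, nS, nS)
  M[dead, dead] <- 1

  if (attained_age >= inputs$econ$max_age) {
    for (i in seq_len(nS - 1)) M[i, dead] <- 1
    return(M)
  }

  qa <- q_for_ages(inputs, inputs$strata$sex[s], attained_age)
  rk <- inputs$mortality$ratio_k
  up <- arm_uptake(arm, inputs)
  u_t <- if (cycle == 1) up[1] else up[2]
  Ptkr <- inputs$transitions$P_tkr[s, , ]
  Pex <- inputs$transitions$P_ex[s, , ]
  rev_p <- inputs$revision[s, ]

  for (j in 1:3) {
    i <- idx_pre(j)
    M[i, dead] <- qa
    srv <- 1 - qa
    for (m in 1:3)
      M[i, idx_prim(1, m)] <- srv * u_t * Ptkr[j, m]
    if (cycle == 1) {
      for (m in 1:3)
        M[i, idx_pre(m)] <- M[i, idx_pre(m)] + srv * (1 - u_t) * Pex[j, m]
    } else {
      M[i, i] <- M[i, i] + srv * (1 - u_t)
    }
  }
  for (k in seq_len(K)) {
    p <- min(1, qa * rk[k])
    k2 <- min(k + 1, K)
    for (j in 1:3) {
      i <- idx_prim(k, j)
      M[i, dead] <- p
      M[i, idx_rev(k2, j, K)] <- (1 - p) * rev_p[k]
      M[i, idx_prim(k2, j)] <- M[i, idx_prim(k2, j)] + (1 - p) * (1 - rev_p[k])
      i <- idx_rev(k, j, K)
      M[i, dead] <- p
      M[i, idx_rev(k2, j, K)] <- M[i, idx_rev(k2, j, K)] + (1 - p)
    }
  }
  M
}

run_stratum <- function(n0_pain, s, arm, inputs, horizon = NULL) {
  K <- inputs$k_max
  nS <- n_expanded_states(K)
  start_age <- inputs$strata$start_age[s]
  sex <- inputs$strata$sex[s]
  max_age <- inputs$econ$max_age
  H_full <- as.integer(max_age - start_age + 1)
  H <- H_full
  if (!is.null(horizon)) {
    if (horizon > H_full)
      message("horizon ", horizon, " exceeds max_age for stratum ",
              inputs$strata$id[s], "; truncated to ", H_full, " cycles")
    H <- min(as.integer(horizon), H_full)
  }

  prim_rng <- (3L + 1L):(3L + 3L * K)
  rev_rng <- (3L + 3L * K + 1L):(3L + 6L * K)
  dead_i <- idx_dead(K)

  occ <- matrix(0, H + 1L, nS)
  occ[1, 1:3] <- n0_pain
  events <- matrix(0, H, 3L,
                   dimnames = list(NULL, c("primaries", "revisions", "deaths")))

  up <- arm_uptake(arm, inputs)
  Ptkr <- inputs$transitions$P_tkr[s, , ]
  Pex <- inputs$transitions$P_ex[s, , ]
  rvec <- inputs$revision[s, ]
  rk <- inputs$mortality$ratio_k
  qs <- q_for_ages(inputs, sex, start_age + seq_len(H) - 1L)
  capped <- FALSE

  for (t in seq_len(H)) {
    age <- start_age + t - 1L
    qa <- qs[t]
    v <- occ[t, ]
    pre <- v[1:3]
    prim <- matrix(v[prim_rng], nrow = 3)
    revm <- matrix(v[rev_rng], nrow = 3)

    pk_raw <- qa * rk
    if (any(pk_raw > 1)) capped <- TRUE
    pk <- pmin(1, pk_raw)
    pre_s <- pre * (1 - qa)
    prim_s <- t(t(prim) * (1 - pk))
    rev_s <- t(t(revm) * (1 - pk))
    deaths <- sum(pre) - sum(pre_s) + sum(prim) - sum(prim_s) +
      sum(revm) - sum(rev_s)

    u_t <- if (t == 1) up[1] else up[2]
    movers <- pre_s * u_t
    primaries <- sum(movers)
    stay <- pre_s - movers
    new_pre <- if (t == 1) as.vector(stay %*% Pex) else stay

    rev_flow <- t(t(prim_s) * rvec)
    revisions <- sum(rev_flow)
    prim_stay <- prim_s - rev_flow

    new_prim <- matrix(0, 3, K)
    new_prim[, 1] <- as.vector(movers %*% Ptkr)
    new_prim[, 2:K] <- new_prim[, 2:K] + prim_stay[, 1:(K - 1)]
    new_prim[, K] <- new_prim[, K] + prim_stay[, K]

    new_rev <- matrix(0, 3, K)
    new_rev[, 2:K] <- rev_flow[, 1:(K - 1)] + rev_s[, 1:(K - 1)]
    new_rev[, K] <- new_rev[, K] + rev_flow[, K] + rev_s[, K]

    newv <- c(new_pre, as.vector(new_prim), as.vector(new_rev),
              v[dead_i] + deaths)
    if (age >= max_age) {
      forced <- sum(newv[-dead_i])
      newv[dead_i] <- newv[dead_i] + forced
      newv[-dead_i] <- 0
      deaths <- deaths + forced
    }
    occ[t + 1L, ] <- newv
    events[t, ] <- c(primaries, revisions, deaths)
  }
  if (capped)
    warning("death probability q * excess ratio exceeded 1 and was capped (",
            "stratum ", inputs$strata$id[s], ")")
  list(stratum = inputs$strata$id[s], start_age = start_age, sex = sex,
       arm = arm, occ = occ, events = as.data.frame(events), horizon = H)
}

#' Run one arm of the cohort model
#'
#' @param arm `"usual_care"` (surgery for the whole surviving cohort in cycle
#'   1) or `"exercise"` (education and exercise program with later optional
#'   surgery).
#' @param cohort An allocated `oa_cohort`.
#' @param inputs An `oa_inputs` object.
#' @param horizon Optional truncation in cycles; by default each stratum runs
#'   to the maximum age.
#' @return An `oa_trajectories` list with one element per stratum, each
#'   containing the occupancy matrix (`cycles + 1` rows over the expanded
#'   state space) and the per-cycle event counts.
#' @export
run_arm <- function(arm = c("usual_care", "exercise"), cohort, inputs,
                    horizon = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(cohort, "oa_cohort"))
  if (is.null(cohort$allocation))
    stop("cohort has no baseline allocation; call allocate_baseline_states()")
  out <- lapply(seq_len(nrow(inputs$strata)), function(s)
    run_stratum(cohort$allocation[s, ], s, arm, inputs, horizon))
  names(out) <- inputs$strata$id
  structure(out, class = "oa_trajectories", arm = arm)
}

#' Half-cycle corrected occupancy
#'
#' Trapezoidal correction: the effective occupancy during cycle `t` is the
#' mean of the occupancies at the start and end of the cycle. Event counts
#' are not corrected.
#'
#' @param occ Occupancy matrix with `H + 1` rows (cycle starts plus the final
#'   end-of-horizon row), or one stratum element of [run_arm()] output.
#' @return An `H x n_states` matrix of effective occupancies.
#' @export
half_cycle_occupancy <- function(occ) {
  if (is.list(occ)) occ <- occ$occ
  H <- nrow(occ) - 1L
  (occ[seq_len(H), , drop = FALSE] + occ[seq_len(H) + 1L, , drop = FALSE]) / 2
}

#' Trajectory as a tidy data frame
#'
#' @param trajectories Output of [run_arm()].
#' @return Data frame with columns `stratum`, `cycle`, `status`, `k`, `pain`,
#'   `persons` (cycle-start occupancy).
#' @export
trajectory_df <- function(trajectories) {
  st <- expanded_states(k_max_from_traj(trajectories))
  do.call(rbind, lapply(trajectories, function(tr) {
    H1 <- nrow(tr$occ)
    data.frame(stratum = tr$stratum,
               cycle = rep(seq_len(H1), each = nrow(st)),
               status = rep(st$status, H1), k = rep(st$k, H1),
               pain = rep(st$pain, H1),
               persons = as.vector(t(tr$occ)))
  }))
}

k_max_from_traj <- function(trajectories) {
  (ncol(trajectories[[1]]$occ) - 4L) / 6L
}
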