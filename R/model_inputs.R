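#' The validated input bundle
#'
#' All model inputs travel in one structure (`oa_inputs`): the stratum table,
#' economic settings, cost and surgery-uptake parameters, utilities,
#' life-table mortality with post-surgical excess ratios, pain-state
#' transition tables per arm, revision probabilities by years since primary
#' surgery, and baseline pain-state proportions with the counts backing their
#' Dirichlet uncertainty. On disk a bundle is a directory of plain CSV files
#' plus one `settings.json`; see [load_input_bundle()].
#'
#' @name oacea-inputs
NULL

BUNDLE_FILES <- c(
  "population.csv", "baseline_proportions.csv", "mortality.csv",
  "excess_mortality.csv", "transitions_tkr.csv", "transitions_exercise.csv",
  "revision.csv", "utilities.csv", "incremental_utilities.csv",
  "settings.json"
)

default_settings <- function() {
  list(
    econ = list(discount_rate = 0.05, wtp_threshold = 28033,
                currency_rate = 0.6947, max_age = 100, cycle_length = 1),
    costs = list(primary_tkr = 24607, primary_tkr_public = 20955,
                 primary_tkr_private = 25435,
                 revision_tkr = 43125, revision_tkr_public = 43233,
                 revision_tkr_private = 43078,
                 nonsurgical_program = 1500, other_annual_cost_delta = 0,
                 surgical_cost_se_frac = 0.15,
                 program_cost_range = c(750, 3000),
                 other_cost_delta_range = c(-500, 500),
                 other_cost_delta_years = 5),
    uptake = list(p_tkr_year1 = 0.26, ci_year1 = c(0.14, 0.38),
                  p_tkr_subsequent = 0.08, ci_subsequent = c(0.03, 0.21)),
    utilities = list(revision_disutility_event = 0.28,
                     revision_disutility_chronic = 0.10,
                     revision_disutility_se_frac = 0.25,
                     incremental_utility_se = 0.03),
    hospital_mix_public = 0.269,
    lognormal_default_sdlog = 0.1,
    dirichlet_smoothing = FALSE,
    k_max = 20,
    start_age_offset = 5
  )
}

# interval table -> per-year ratio vector over k = 1..k_max
ratio_by_year <- function(intervals, k_max) {
  out <- numeric(k_max)
  for (k in seq_len(k_max)) {
    hit <- which(intervals$years_from <= k &
                   (is.infinite(intervals$years_to) | k <= intervals$years_to))
    if (length(hit) == 0)
      stop("excess_mortality intervals do not cover year ", k)
    out[k] <- intervals$ratio[hit[1]]
  }
  out
}

new_inputs <- function(strata, settings, population, baseline, mortality,
                       transitions, revision, utilities) {
  x <- list(
    strata = strata,
    econ = settings$econ,
    costs = settings$costs,
    uptake = settings$uptake,
    utilities = utilities,
    mortality = mortality,
    transitions = transitions,
    revision = revision,
    baseline = baseline,
    population = population,
    hospital_mix_public = settings$hospital_mix_public,
    lognormal_default_sdlog = settings$lognormal_default_sdlog,
    dirichlet_smoothing = isTRUE(settings$dirichlet_smoothing),
    k_max = as.integer(settings$k_max),
    start_age_offset = settings$start_age_offset
  )
  x$mortality$ratio_k <- ratio_by_year(x$mortality$intervals, x$k_max)
  class(x) <- "oa_inputs"
  x
}

#' @export
print.oa_inputs <- function(x, ...) {
  cat("<oa_inputs>\n")
  cat(sprintf("  strata: %d (%s x %s)\n", nrow(x$strata),
              paste(AGE_BANDS, collapse = "/"), paste(SEXES, collapse = "/")))
  cat(sprintf("  eligible cohort: %.0f persons\n",
              sum(x$population$population * x$population$tkr_rate)))
  cat(sprintf("  discount %.1f%%, lambda A$%s/QALY, max age %d, k_max %d\n",
              100 * x$econ$discount_rate,
              format(x$econ$wtp_threshold, big.mark = " "),
              x$econ$max_age, x$k_max))
  invisible(x)
}

#' Validate an input bundle
#'
#' Checks every structural invariant the model relies on: transition rows sum
#' to one over alive destinations, baseline proportions sum to one, death
#' probabilities lie in `[0, 1)` and cover every attained age, CI bounds
#' bracket their means, weighted costs lie between their public and private
#' components, and utilities do not exceed one.
#'
#' @param x An `oa_inputs` object.
#' @return `x`, invisibly; stops with an informative error naming the
#'   offending table and cell otherwise.
#' @export
validate_inputs <- function(x) {
  stopifnot(inherits(x, "oa_inputs"))
  ids <- x$strata$id
  if (nrow(x$strata) != 8 || anyDuplicated(ids))
    stop("strata: expected the 8 unique age-band x sex strata")
  lower <- as.integer(sub("-.*", "", x$strata$age_band))
  upper <- as.integer(sub(".*-", "", x$strata$age_band))
  if (any(x$strata$start_age < lower | x$strata$start_age > upper))
    stop("strata: start_age outside its age band")

  ec <- x$econ
  if (ec$discount_rate < 0 || ec$discount_rate >= 1)
    stop("settings.json: discount_rate must be in [0, 1)")
  if (ec$wtp_threshold <= 0) stop("settings.json: wtp_threshold must be > 0")
  if (ec$currency_rate <= 0) stop("settings.json: currency_rate must be > 0")

  cs <- x$costs
  cost_fields <- c("primary_tkr", "primary_tkr_public", "primary_tkr_private",
                   "revision_tkr", "revision_tkr_public",
                   "revision_tkr_private", "nonsurgical_program")
  for (f in cost_fields)
    if (cs[[f]] < 0) stop("settings.json: cost ", f, " must be nonnegative")
  rng <- function(a, b) c(min(a, b), max(a, b))
  pr <- rng(cs$primary_tkr_public, cs$primary_tkr_private)
  if (cs$primary_tkr < pr[1] - 1e-9 || cs$primary_tkr > pr[2] + 1e-9)
    stop("settings.json: weighted primary cost outside public/private range")
  rr <- rng(cs$revision_tkr_public, cs$revision_tkr_private)
  if (cs$revision_tkr < rr[1] - 1e-9 || cs$revision_tkr > rr[2] + 1e-9)
    stop("settings.json: weighted revision cost outside public/private range")

  up <- x$uptake
  for (nm in c("p_tkr_year1", "p_tkr_subsequent"))
    if (up[[nm]] <= 0 || up[[nm]] >= 1)
      stop("settings.json: uptake ", nm, " must be in (0, 1)")
  if (!(up$ci_year1[1] <= up$p_tkr_year1 && up$p_tkr_year1 <= up$ci_year1[2]))
    stop("settings.json: year-1 uptake CI does not bracket the mean")
  if (!(up$ci_subsequent[1] <= up$p_tkr_subsequent &&
        up$p_tkr_subsequent <= up$ci_subsequent[2]))
    stop("settings.json: subsequent-year uptake CI does not bracket the mean")

  ut <- x$utilities
  if (any(ut$u_base > 1 + 1e-12) || any(ut$u_post > 1 + 1e-12))
    stop("utilities.csv: utilities must not exceed 1")
  if (ut$revision_disutility_event < 0 || ut$revision_disutility_chronic < 0)
    stop("settings.json: revision disutilities must be nonnegative")

  q <- x$mortality$q
  if (any(q < 0) || any(q >= 1))
    stop("mortality.csv: q must lie in [0, 1)")
  ages <- as.integer(rownames(q))
  need <- seq(min(x$strata$start_age), x$econ$max_age - 1L)
  if (!all(need %in% ages))
    stop("mortality.csv: ages must cover ",
         min(need), "..", max(need))
  if (any(x$mortality$intervals$ratio <= 0))
    stop("excess_mortality.csv: ratios must be positive")

  for (arm in c("tkr", "exercise")) {
    P <- if (arm == "tkr") x$transitions$P_tkr else x$transitions$P_ex
    if (any(P < -1e-12) || any(P > 1 + 1e-12))
      stop("transitions_", arm, ".csv: probabilities outside [0, 1]")
    rs <- apply(P, c(1, 2), sum)
    bad <- which(abs(rs - 1) > 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "transitions_%s.csv: row (%s, from %s) sums to %.12f, expected 1",
        arm, ids[bad[1, 1]], HEALTH_STATES[bad[1, 2]], rs[bad[1, 1], bad[1, 2]]))
  }

  if (any(x$revision < 0) || any(x$revision > 1))
    stop("revision.csv: probabilities outside [0, 1]")

  ps <- rowSums(x$baseline$pi)
  bad <- which(abs(ps - 1) > 1e-9)
  if (length(bad) > 0)
    stop(sprintf(
      "baseline_proportions.csv: proportions for stratum %s sum to %.12f, expected 1",
      ids[bad[1]], ps[bad[1]]))

  if (any(x$population$population < 0) || any(x$population$tkr_rate < 0))
    stop("population.csv: populations and rates must be nonnegative")
  if (x$hospital_mix_public < 0 || x$hospital_mix_public > 1)
    stop("settings.json: hospital_mix_public must be in [0, 1]")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"), sprintf("%.17g", x))
}

write_bundle_csv <- function(df, num_cols, path) {
  for (cl in num_cols) df[[cl]] <- fmt_num(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write an input bundle to a directory
#'
#' Serializes an `oa_inputs` object into the standard bundle layout (nine CSV
#' files plus `settings.json`). Numeric fields are written with 17 significant
#' digits so a load/write/load round trip is lossless.
#'
#' @param inputs An `oa_inputs` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(inputs, dir) {
  stopifnot(inherits(inputs, "oa_inputs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- inputs$strata
  ids <- st$id

  write_bundle_csv(
    data.frame(age_band = st$age_band, sex = st$sex,
               population = inputs$population$population,
               tkr_rate = inputs$population$tkr_rate),
    c("population", "tkr_rate"), file.path(dir, "population.csv"))

  bp <- expand.grid(state = HEALTH_STATES, id = ids,
                    stringsAsFactors = FALSE)
  bp <- data.frame(
    age_band = st$age_band[match(bp$id, ids)],
    sex = st$sex[match(bp$id, ids)],
    state = bp$state,
    proportion = as.vector(t(inputs$baseline$pi)),
    count = as.vector(t(inputs$baseline$counts)))
  write_bundle_csv(bp, c("proportion", "count"),
                   file.path(dir, "baseline_proportions.csv"))

  q <- inputs$mortality$q
  mt <- data.frame(age = rep(as.integer(rownames(q)), times = ncol(q)),
                   sex = rep(colnames(q), each = nrow(q)),
                   q = as.vector(q))
  write_bundle_csv(mt, "q", file.path(dir, "mortality.csv"))

  write_bundle_csv(inputs$mortality$intervals,
                   c("years_from", "years_to", "ratio", "sdlog"),
                   file.path(dir, "excess_mortality.csv"))

  write_trans <- function(P, counts, file) {
    g <- expand.grid(to_state = HEALTH_STATES, from_state = HEALTH_STATES,
                     id = ids, stringsAsFactors = FALSE)
    g <- data.frame(
      age_band = st$age_band[match(g$id, ids)],
      sex = st$sex[match(g$id, ids)],
      from_state = g$from_state, to_state = g$to_state,
      probability = as.vector(aperm(P, c(3, 2, 1))),
      count = as.vector(aperm(counts, c(3, 2, 1))))
    write_bundle_csv(g, c("probability", "count"), file.path(dir, file))
  }
  write_trans(inputs$transitions$P_tkr, inputs$transitions$counts_tkr,
              "transitions_tkr.csv")
  write_trans(inputs$transitions$P_ex, inputs$transitions$counts_ex,
              "transitions_exercise.csv")

  rv <- expand.grid(year = seq_len(inputs$k_max), id = ids,
                    stringsAsFactors = FALSE)
  rv <- data.frame(
    age_band = st$age_band[match(rv$id, ids)],
    sex = st$sex[match(rv$id, ids)],
    year = rv$year,
    probability = as.vector(t(inputs$revision)))
  write_bundle_csv(rv, "probability", file.path(dir, "revision.csv"))

  uu <- rbind(
    data.frame(context = "baseline",
               expand.grid(state = HEALTH_STATES, id = ids,
                           stringsAsFactors = FALSE),
               utility = as.vector(t(inputs$utilities$u_base))),
    data.frame(context = "post_tkr",
               expand.grid(state = HEALTH_STATES, id = ids,
                           stringsAsFactors = FALSE),
               utility = as.vector(t(inputs$utilities$u_post))))
  uu <- data.frame(age_band = st$age_band[match(uu$id, ids)],
                   sex = st$sex[match(uu$id, ids)],
                   state = uu$state, context = uu$context,
                   utility = uu$utility)
  write_bundle_csv(uu, "utility", file.path(dir, "utilities.csv"))

  du <- expand.grid(to_state = HEALTH_STATES, from_state = HEALTH_STATES,
                    stringsAsFactors = FALSE)[, c(2, 1)]
  du$delta <- as.vector(t(inputs$utilities$du))
  write_bundle_csv(du, "delta", file.path(dir, "incremental_utilities.csv"))

  settings <- list(
    econ = inputs$econ, costs = inputs$costs, uptake = inputs$uptake,
    utilities = inputs$utilities[c("revision_disutility_event",
                                   "revision_disutility_chronic",
                                   "revision_disutility_se_frac",
                                   "incremental_utility_se")],
    hospital_mix_public = inputs$hospital_mix_public,
    lognormal_default_sdlog = inputs$lognormal_default_sdlog,
    dirichlet_smoothing = inputs$dirichlet_smoothing,
    k_max = inputs$k_max,
    start_age_offset = inputs$start_age_offset)
  jsonlite::write_json(settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_bundle_csv <- function(dir, file, cols) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("input bundle is missing ", file)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(file, ": missing column(s) ", paste(missing, collapse = ", "))
  df
}

#' Load and validate an input bundle
#'
#' Reads the standard bundle layout -- `population.csv`,
#' `baseline_proportions.csv`, `mortality.csv`, `excess_mortality.csv`,
#' `transitions_tkr.csv`, `transitions_exercise.csv`, `revision.csv`,
#' `utilities.csv`, `incremental_utilities.csv` and `settings.json` -- from a
#' directory, assembles an `oa_inputs` object and runs [validate_inputs()].
#' Probabilities are decimals; money is in 2022 Australian dollars.
#'
#' @param path Bundle directory.
#' @param dirichlet_smoothing Optional override of the bundle's Dirichlet
#'   +1-smoothing flag.
#' @return A validated `oa_inputs` object.
#' @export
load_input_bundle <- function(path, dirichlet_smoothing = NULL) {
  if (!dir.exists(path)) stop("input bundle directory not found: ", path)
  sp <- file.path(path, "settings.json")
  if (!file.exists(sp)) stop("input bundle is missing settings.json")
  settings <- jsonlite::read_json(sp, simplifyVector = TRUE)
  def <- default_settings()
  settings <- utils::modifyList(def, settings)
  if (!is.null(dirichlet_smoothing))
    settings$dirichlet_smoothing <- isTRUE(dirichlet_smoothing)

  strata <- default_strata(settings$start_age_offset)
  ids <- strata$id
  key <- function(df) paste(df$age_band, df$sex, sep = "_")
  k_max <- as.integer(settings$k_max)

  pop <- read_bundle_csv(path, "population.csv",
                         c("age_band", "sex", "population", "tkr_rate"))
  m <- match(ids, key(pop))
  if (anyNA(m)) stop("population.csv: missing stratum ", ids[which(is.na(m))[1]])
  population <- data.frame(id = ids, population = pop$population[m],
                           tkr_rate = pop$tkr_rate[m])

  bp <- read_bundle_csv(path, "baseline_proportions.csv",
                        c("age_band", "sex", "state", "proportion", "count"))
  pi0 <- counts0 <- matrix(NA_real_, 8, 3, dimnames = list(ids, HEALTH_STATES))
  mm <- match(paste(key(bp), bp$state), paste(rep(ids, each = 3),
                                              rep(HEALTH_STATES, 8)))
  if (anyNA(mm) || length(mm) != 24)
    stop("baseline_proportions.csv: expected one row per stratum x state")
  pi0[cbind((mm - 1) %/% 3 + 1, (mm - 1) %% 3 + 1)] <- bp$proportion
  counts0[cbind((mm - 1) %/% 3 + 1, (mm - 1) %% 3 + 1)] <- bp$count
  baseline <- list(pi = pi0, counts = counts0)

  mt <- read_bundle_csv(path, "mortality.csv", c("age", "sex", "q"))
  ages <- sort(unique(mt$age))
  q <- matrix(NA_real_, length(ages), 2, dimnames = list(ages, SEXES))
  q[cbind(match(mt$age, ages), match(mt$sex, SEXES))] <- mt$q
  if (anyNA(q)) stop("mortality.csv: incomplete age x sex grid")

  em <- read_bundle_csv(path, "excess_mortality.csv",
                        c("years_from", "years_to", "ratio"))
  if (is.null(em$sdlog)) em$sdlog <- settings$lognormal_default_sdlog
  em$years_to[is.na(em$years_to)] <- Inf
  mortality <- list(q = q, intervals = em,
                    default_sdlog = settings$lognormal_default_sdlog)

  read_trans <- function(file) {
    tr <- read_bundle_csv(path, file, c("age_band", "sex", "from_state",
                                        "to_state", "probability", "count"))
    P <- counts <- array(NA_real_, c(8, 3, 3),
                         dimnames = list(ids, HEALTH_STATES, HEALTH_STATES))
    i <- match(key(tr), ids)
    j <- match(tr$from_state, HEALTH_STATES)
    k <- match(tr$to_state, HEALTH_STATES)
    if (anyNA(i) || anyNA(j) || anyNA(k))
      stop(file, ": unrecognized stratum or state label")
    P[cbind(i, j, k)] <- tr$probability
    counts[cbind(i, j, k)] <- tr$count
    if (anyNA(P)) stop(file, ": incomplete stratum x from x to grid")
    list(P = P, counts = counts)
  }
  t_tkr <- read_trans("transitions_tkr.csv")
  t_ex <- read_trans("transitions_exercise.csv")
  transitions <- list(P_tkr = t_tkr$P, counts_tkr = t_tkr$counts,
                      P_ex = t_ex$P, counts_ex = t_ex$counts)

  rv <- read_bundle_csv(path, "revision.csv",
                        c("age_band", "sex", "year", "probability"))
  revision <- matrix(NA_real_, 8, k_max,
                     dimnames = list(ids, seq_len(k_max)))
  revision[cbind(match(key(rv), ids), rv$year)] <- rv$probability
  if (anyNA(revision)) stop("revision.csv: incomplete stratum x year grid")

  uu <- read_bundle_csv(path, "utilities.csv",
                        c("age_band", "sex", "state", "context", "utility"))
  u_base <- u_post <- matrix(NA_real_, 8, 3,
                             dimnames = list(ids, HEALTH_STATES))
  for (r in seq_len(nrow(uu))) {
    i <- match(key(uu)[r], ids); j <- match(uu$state[r], HEALTH_STATES)
    if (is.na(i) || is.na(j))
      stop("utilities.csv: unrecognized stratum or state in row ", r)
    if (uu$context[r] == "baseline") u_base[i, j] <- uu$utility[r]
    else if (uu$context[r] == "post_tkr") u_post[i, j] <- uu$utility[r]
    else stop("utilities.csv: unknown context ", uu$context[r])
  }
  if (anyNA(u_base) || anyNA(u_post))
    stop("utilities.csv: incomplete stratum x state x context grid")

  duf <- read_bundle_csv(path, "incremental_utilities.csv",
                         c("from_state", "to_state", "delta"))
  du <- matrix(NA_real_, 3, 3, dimnames = list(HEALTH_STATES, HEALTH_STATES))
  du[cbind(match(duf$from_state, HEALTH_STATES),
           match(duf$to_state, HEALTH_STATES))] <- duf$delta
  if (anyNA(du)) stop("incremental_utilities.csv: incomplete from x to grid")

  utilities <- c(list(u_base = u_base, u_post = u_post, du = du),
                 settings$utilities[c("revision_disutility_event",
                                      "revision_disutility_chronic",
                                      "revision_disutility_se_frac",
                                      "incremental_utility_se")])

  x <- new_inputs(strata, settings, population, baseline, mortality,
                  transitions, revision, utilities)
  validate_inputs(x)
}
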