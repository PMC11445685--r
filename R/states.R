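#' Health states, strata and the expanded state space
#'
#' The model's alive health states are defined by the pain domain of the
#' EQ-5D-5L: no or mild pain, moderate pain, severe or extreme pain; dead is
#' the absorbing fourth state. The cohort engine runs on an expanded state
#' space that crosses pain with surgical status: pre-surgical (enrolled in the
#' education and exercise program), post-primary-replacement tunnel states
#' indexed by years since the primary procedure (k = 1..k_max), and
#' post-revision tunnel states which retain the years-since-primary clock so
#' that the post-surgical excess-mortality ratio stays well defined.
#'
#' @name oacea-states
#' @keywords internal
NULL

HEALTH_STATES <- c("no_mild", "moderate", "severe_extreme")
AGE_BANDS <- c("45-54", "55-64", "65-74", "75-84")
SEXES <- c("female", "male")

N_PAIN <- 3L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratum table
#'
#' The eight (age band x sex) strata covering the model population, with the
#' single-year starting age used to index the life table.
#'
#' @param start_age_offset Years added to the band lower bound to obtain the
#'   starting age (default 5, the band midpoint).
#' @return A data frame with columns `id`, `age_band`, `sex`, `start_age`.
#' @export
default_strata <- function(start_age_offset = 5) {
  g <- expand.grid(sex = SEXES, age_band = AGE_BANDS,
                   stringsAsFactors = FALSE)
  g <- g[, c("age_band", "sex")]
  lower <- as.integer(sub("-.*", "", g$age_band))
  data.frame(
    id = paste(g$age_band, g$sex, sep = "_"),
    age_band = g$age_band,
    sex = g$sex,
    start_age = lower + as.integer(start_age_offset),
    stringsAsFactors = FALSE
  )
}

# --- expanded state space indexing -----------------------------------------
# Layout (k_max = K):
#   1..3                     pre-surgical, by pain state
#   3 + (k-1)*3 + pain       post-primary, year-since-primary k = 1..K
#   3 + K*3 + (k-1)*3 + pain post-revision, year-since-primary k = 1..K
#   3 + 2*K*3 + 1            dead

idx_pre <- function(pain) pain
idx_prim <- function(k, pain) 3L + (k - 1L) * 3L + pain
idx_rev <- function(k, pain, k_max) 3L + k_max * 3L + (k - 1L) * 3L + pain
idx_dead <- function(k_max) 3L + 2L * k_max * 3L + 1L
n_expanded_states <- function(k_max) 3L + 2L * k_max * 3L + 1L

#' Expanded state table
#'
#' Enumerates the expanded state space used by the cohort engine.
#'
#' @param k_max Number of years-since-primary tunnel states.
#' @return Data frame with columns `index`, `status` (one of `"pre"`,
#'   `"post_primary"`, `"post_revision"`, `"dead"`), `k` (years since primary;
#'   `NA` for pre/dead) and `pain`.
#' @export
expanded_states <- function(k_max = 20L) {
  k_max <- as.integer(k_max)
  pre <- data.frame(index = idx_pre(1:3), status = "pre", k = NA_integer_,
                    pain = HEALTH_STATES, stringsAsFactors = FALSE)
  prim <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    data.frame(index = idx_prim(k, 1:3), status = "post_primary", k = k,
               pain = HEALTH_STATES, stringsAsFactors = FALSE)
  }))
  rev <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    data.frame(index = idx_rev(k, 1:3, k_max), status = "post_revision",
               k = k, pain = HEALTH_STATES, stringsAsFactors = FALSE)
  }))
  dead <- data.frame(index = idx_dead(k_max), status = "dead",
                     k = NA_integer_, pain = NA_character_,
                     stringsAsFactors = FALSE)
  out <- rbind(pre, prim, rev, dead)
  rownames(out) <- NULL
  out
}
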