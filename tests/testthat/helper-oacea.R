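# Shared fixtures: synthetic bundles are deterministic given the seed, so we
# memoise them per session instead of regenerating in every test.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

base_inputs <- function(seed = 1)
  memo(paste0("ref", seed), generate_input_bundle(seed, "registry_like"))

null_inputs <- function(seed = 2)
  memo(paste0("null", seed), generate_input_bundle(seed, "null_effect"))

# degenerate test bed: constant mortality, flat utilities, no revisions, no
# excess mortality -- closed forms become available
flat_inputs <- function(q = 0, utility = 1, uptake1 = NULL, uptake2 = NULL) {
  x <- base_inputs(1)
  x$mortality$q[] <- q
  x$mortality$intervals$ratio <- rep(1, nrow(x$mortality$intervals))
  x$mortality$ratio_k[] <- 1
  x$revision[] <- 0
  x$utilities$u_base[] <- utility
  x$utilities$u_post[] <- utility
  x$utilities$du[] <- 0
  x$utilities$revision_disutility_event <- 0
  x$utilities$revision_disutility_chronic <- 0
  if (!is.null(uptake1)) x$uptake$p_tkr_year1 <- uptake1
  if (!is.null(uptake2)) x$uptake$p_tkr_subsequent <- uptake2
  x
}

PAIN_STATES <- c("no_mild", "moderate", "severe_extreme")

# cohort with all mass in one (stratum, state) cell
point_cohort <- function(inputs, s = 1, state = 1, n = 1) {
  a <- matrix(0, 8, 3, dimnames = list(inputs$strata$id, PAIN_STATES))
  a[s, state] <- n
  structure(list(n_eligible = rowSums(a), total_n = n, allocation = a),
            class = "oa_cohort")
}
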