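#' Build the hypothetical national cohort
#'
#' The modelled population is everyone who would otherwise undergo a primary
#' total knee replacement in one year: per stratum, population count times
#' the age- and sex-specific procedure rate. Persons are carried as
#' continuous masses throughout the cohort model; rounding happens only at
#' report rendering.
#'
#' @param population Named numeric vector (or the `population` column of an
#'   `oa_inputs` population table) of persons per stratum.
#' @param tkr_rate Named numeric vector of procedures per person-year,
#'   aligned with `population`.
#' @return An `oa_cohort`: list with `n_eligible` (named per-stratum vector),
#'   `total_n`, and `allocation` (`NULL` until
#'   [allocate_baseline_states()] fills it).
#' @export
size_eligible_cohort <- function(population, tkr_rate) {
  if (length(population) != length(tkr_rate))
    stop("population and tkr_rate must align")
  if (any(population < 0) || any(tkr_rate < 0))
    stop("populations and rates must be nonnegative")
  n <- population * tkr_rate
  names(n) <- names(population) %||% names(tkr_rate)
  structure(list(n_eligible = n, total_n = sum(n), allocation = NULL),
            class = "oa_cohort")
}

#' Allocate the eligible cohort to baseline pain states
#'
#' @param cohort An `oa_cohort` from [size_eligible_cohort()].
#' @param baseline_proportions Strata x alive-state matrix of proportions,
#'   each row summing to 1.
#' @return The cohort with `allocation` filled (persons per stratum x state).
#' @export
allocate_baseline_states <- function(cohort, baseline_proportions) {
  stopifnot(inherits(cohort, "oa_cohort"))
  p <- as.matrix(baseline_proportions)
  if (nrow(p) != length(cohort$n_eligible))
    stop("baseline proportions must have one row per stratum")
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > 1e-9 & cohort$n_eligible > 0)
  if (length(bad) > 0)
    stop("baseline proportions for stratum ",
         (rownames(p) %||% seq_len(nrow(p)))[bad[1]],
         " sum to ", format(rs[bad[1]], digits = 12), ", expected 1")
  cohort$allocation <- p * cohort$n_eligible
  dimnames(cohort$allocation) <- list(names(cohort$n_eligible),
                                      colnames(p) %||% HEALTH_STATES)
  cohort
}

#' Construct the default cohort implied by an input bundle
#'
#' @param inputs An `oa_inputs` object.
#' @return An `oa_cohort` with the baseline allocation filled.
#' @export
build_cohort <- function(inputs) {
  stopifnot(inherits(inputs, "oa_inputs"))
  pop <- stats::setNames(inputs$population$population, inputs$population$id)
  rate <- stats::setNames(inputs$population$tkr_rate, inputs$population$id)
  allocate_baseline_states(size_eligible_cohort(pop, rate),
                           inputs$baseline$pi)
}

#' @export
print.oa_cohort <- function(x, ...) {
  cat(sprintf("<oa_cohort> %.0f eligible persons in %d strata%s\n",
              x$total_n, length(x$n_eligible),
              if (is.null(x$allocation)) " (unallocated)" else ""))
  invisible(x)
}
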