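#' Subgroup analyses and report rendering
#'
#' Subgroups rerun the model with the baseline allocation restricted to the
#' subgroup: baseline pain state, age band and sex partitions restrict the
#' cohort mass (and, the engine being linear in the initial allocation, sum
#' exactly back to the base case); hospital-type subgroups keep the full
#' case mix but apply type-specific procedure costs and the public/private
#' split of the cohort.
#'
#' @name oacea-reporting
NULL

subgroup_result_row <- function(partition, group, res) {
  n <- res$total_n
  data.frame(
    partition = partition, group = group, n = n,
    cost_exercise = res$arms$exercise$totals$cost,
    cost_usual_care = res$arms$usual_care$totals$cost,
    delta_cost = res$delta_cost,
    qalys_exercise = res$arms$exercise$totals$qalys,
    qalys_usual_care = res$arms$usual_care$totals$qalys,
    delta_qalys = res$delta_qalys,
    delta_cost_pp = res$per_person$delta_cost,
    delta_qalys_pp = res$per_person$delta_qalys,
    inmb_pp = res$per_person$inmb,
    stringsAsFactors = FALSE)
}

restrict_cohort <- function(cohort, keep_strata = NULL, keep_state = NULL) {
  a <- cohort$allocation
  if (!is.null(keep_strata)) a[!(rownames(a) %in% keep_strata), ] <- 0
  if (!is.null(keep_state)) a[, setdiff(colnames(a), keep_state)] <- 0
  structure(list(n_eligible = rowSums(a), total_n = sum(a), allocation = a),
            class = "oa_cohort")
}

#' Run the subgroup analyses
#'
#' @param inputs An `oa_inputs` object.
#' @param by Partitions to run: any of `"state"`, `"age_band"`, `"sex"`,
#'   `"hospital"`.
#' @param cohort Optional base cohort.
#' @param lambda Threshold; defaults to the bundle's.
#' @return Data frame with one row per subgroup (plus the base case), with
#'   cohort totals and per-person incrementals. Empty subgroups are reported
#'   as `n = 0` rows.
#' @export
run_subgroups <- function(inputs, by = c("state", "age_band", "sex", "hospital"),
                          cohort = NULL, lambda = NULL) {
  by <- match.arg(by, several.ok = TRUE)
  cohort <- cohort %||% build_cohort(inputs)
  lambda <- lambda %||% inputs$econ$wtp_threshold
  rows <- list(subgroup_result_row("base", "base",
                                   oa_run(inputs, cohort, lambda)))
  run_sub <- function(partition, group, sub_cohort, sub_inputs = inputs) {
    if (sub_cohort$total_n == 0) {
      r <- subgroup_result_row(partition, group,
                               structure(list(
                                 total_n = 0,
                                 arms = list(
                                   exercise = list(totals = list(cost = 0, qalys = 0)),
                                   usual_care = list(totals = list(cost = 0, qalys = 0))),
                                 delta_cost = 0, delta_qalys = 0,
                                 per_person = list(delta_cost = NA_real_,
                                                   delta_qalys = NA_real_,
                                                   inmb = NA_real_)),
                                 class = "oa_result"))
      return(r)
    }
    subgroup_result_row(partition, group, oa_run(sub_inputs, sub_cohort, lambda))
  }
  if ("state" %in% by)
    for (st in HEALTH_STATES)
      rows[[length(rows) + 1]] <-
        run_sub("state", st, restrict_cohort(cohort, keep_state = st))
  if ("age_band" %in% by)
    for (ab in AGE_BANDS) {
      keep <- inputs$strata$id[inputs$strata$age_band == ab]
      rows[[length(rows) + 1]] <-
        run_sub("age_band", ab, restrict_cohort(cohort, keep_strata = keep))
    }
  if ("sex" %in% by)
    for (sx in SEXES) {
      keep <- inputs$strata$id[inputs$strata$sex == sx]
      rows[[length(rows) + 1]] <-
        run_sub("sex", sx, restrict_cohort(cohort, keep_strata = keep))
    }
  if ("hospital" %in% by) {
    mix <- inputs$hospital_mix_public
    for (hp in c("public", "private")) {
      frac <- if (hp == "public") mix else 1 - mix
      sub_cohort <- cohort
      sub_cohort$allocation <- cohort$allocation * frac
      sub_cohort$n_eligible <- cohort$n_eligible * frac
      sub_cohort$total_n <- cohort$total_n * frac
      xi <- inputs
      xi$costs$primary_tkr <- inputs$costs[[paste0("primary_tkr_", hp)]]
      xi$costs$revision_tkr <- inputs$costs[[paste0("revision_tkr_", hp)]]
      rows[[length(rows) + 1]] <- run_sub("hospital", hp, sub_cohort, xi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published base-case and subgroup results
#'
#' Returns the transcription of the published lifetime results table and the
#' headline results-text numbers packaged with `oacea` (2022 A$), used by
#' [consistency_report()] to check the arithmetic identities among the
#' printed values.
#'
#' @return List with `table2` (data frame) and `headline` (named vector).
#' @export
oa_published <- function() {
  t2 <- utils::read.csv(system.file("extdata", "published_results.csv",
                                    package = "oacea"),
                        stringsAsFactors = FALSE)
  hl <- utils::read.csv(system.file("extdata", "published_headline.csv",
                                    package = "oacea"),
                        stringsAsFactors = FALSE)
  list(table2 = t2, headline = stats::setNames(hl$value, hl$name))
}

check_row <- function(check, computed, printed, tol_rel = 0.001, tol_abs = 1) {
  rel <- abs(computed - printed) / max(abs(printed), .Machine$double.eps)
  data.frame(check = check, computed = computed, printed = printed,
             rel_err = rel,
             pass = rel <= tol_rel | abs(computed - printed) <= tol_abs,
             stringsAsFactors = FALSE)
}

#' Arithmetic-consistency checks on the published results
#'
#' Verifies the identities that tie the printed numbers together: per-person
#' values equal cohort totals divided by n, the INMB identity
#' `lambda * dQALY - dCost` reproduces each printed INMB, the fewer-procedure
#' components sum, the surgery-avoidance percentage equals fewer primaries
#' over cohort n, and the printed currency conversions follow from the A$
#' values at the published exchange rate. Deviations beyond 0.1% (or A$1,
#' absorbing printed rounding of near-zero values) are flagged.
#'
#' @param published Output of [oa_published()] (or a same-shaped list).
#' @param lambda Willingness-to-pay threshold (A$/QALY).
#' @param currency_rate USD per A$.
#' @return Data frame of checks with computed value, printed value, relative
#'   error and pass flag.
#' @export
consistency_report <- function(published = oa_published(), lambda = 28033,
                               currency_rate = 0.6947) {
  t2 <- published$table2
  hl <- published$headline
  out <- list()
  for (i in seq_len(nrow(t2))) {
    r <- t2[i, ]
    lab <- paste0(r$partition, "/", r$group)
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": per-person cost (program) = total/n"),
      r$total_cost_nonsurgical / r$n, r$per_person_cost_nonsurgical)
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": per-person cost (usual care) = total/n"),
      r$total_cost_usual / r$n, r$per_person_cost_usual)
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": per-person cost difference = total/n"),
      r$delta_cost / r$n, r$per_person_delta_cost)
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": incremental cost = program - usual care"),
      r$total_cost_nonsurgical - r$total_cost_usual, r$delta_cost,
      tol_abs = 2)
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": QALY difference = program - usual care"),
      r$total_qalys_nonsurgical - r$total_qalys_usual, r$delta_qalys,
      tol_abs = 2)
    # printed-rounding propagation: +/-0.5 on the printed INMB itself plus
    # +/-0.5 whole-QALY rounding of the printed total, worth 0.5*lambda/n
    out[[length(out) + 1]] <- check_row(
      paste0(lab, ": INMB = lambda*dQALY - dCost (per person)"),
      compute_inmb(r$delta_cost / r$n, r$delta_qalys / r$n, lambda),
      r$inmb, tol_abs = 0.5 + 0.5 * lambda / r$n)
  }
  base <- t2[t2$group == "base", ]
  out[[length(out) + 1]] <- check_row(
    "headline: fewer primaries + fewer revisions = fewer procedures",
    hl[["fewer_primary_tkr"]] + hl[["fewer_revision_tkr"]],
    hl[["fewer_tkr_total"]], tol_abs = 0.5)
  out[[length(out) + 1]] <- check_row(
    "headline: surgery-avoidance % = fewer primaries / n",
    100 * hl[["fewer_primary_tkr"]] / base$n, hl[["tkr_avoidance_pct"]],
    tol_abs = 0.05)
  out[[length(out) + 1]] <- check_row(
    "headline: per-person saving = total saving / n",
    -base$delta_cost / base$n, hl[["per_person_saving"]])
  out[[length(out) + 1]] <- check_row(
    "headline: per-person QALY loss = total / n",
    -base$delta_qalys / base$n, hl[["per_person_qaly_loss"]],
    tol_abs = 0.005)
  conv <- list(c("primary cost A$ -> $", 24607, "primary_cost_usd"),
               c("revision cost A$ -> $", 43125, "revision_cost_usd"),
               c("threshold A$ -> $", 28033, "threshold_usd"))
  for (cc in conv)
    out[[length(out) + 1]] <- check_row(
      paste0("currency: ", cc[[1]]),
      convert_currency(as.numeric(cc[[2]]), currency_rate),
      hl[[cc[[3]]]])
  do.call(rbind, out)
}

#' Rounded display table for a model run
#'
#' Dollars are rounded to whole units, QALYs to 2 decimals.
#'
#' @param res An `oa_result`.
#' @return One-row data frame in A$ and USD.
#' @export
render_results <- function(res) {
  usd <- function(a) round(convert_currency(a, res$currency_rate))
  data.frame(
    n = round(res$total_n),
    cost_exercise_aud = round(res$arms$exercise$totals$cost),
    cost_usual_aud = round(res$arms$usual_care$totals$cost),
    delta_cost_aud = round(res$delta_cost),
    delta_cost_usd = usd(res$delta_cost),
    qalys_exercise = round(res$arms$exercise$totals$qalys, 2),
    qalys_usual = round(res$arms$usual_care$totals$qalys, 2),
    delta_qalys = round(res$delta_qalys, 2),
    delta_cost_pp_aud = round(res$per_person$delta_cost),
    delta_qalys_pp = round(res$per_person$delta_qalys, 2),
    inmb_pp_aud = round(res$per_person$inmb),
    inmb_pp_usd = usd(res$per_person$inmb))
}

#' Write the standard CSV outputs for a run
#'
#' @param res An `oa_result`.
#' @param dir Output directory.
#' @param psa Optional `oa_psa` whose draws and acceptability curve are also
#'   written.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(res, dir, psa = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(render_results(res), file.path(dir, "results.csv"),
                   row.names = FALSE)
  hs <- horizon_sweep(res)
  utils::write.csv(hs, file.path(dir, "horizon_curve.csv"), row.names = FALSE)
  if (!is.null(psa)) {
    utils::write.csv(psa$draws, file.path(dir, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  }
  invisible(dir)
}
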