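#' Sampling distributions fitted to reported summary statistics
#'
#' Model inputs are published as base-case values with uncertainty expressed
#' as 95% CIs (probabilities), standard errors (costs, disutilities) or
#' category counts (proportions). These constructors fit the distribution
#' family assigned to each input -- Beta, Gamma, Dirichlet, log-normal -- by
#' moment matching so that the analytic mean of the fitted distribution
#' reproduces the base-case value.
#'
#' @name oacea-distributions
NULL

new_dist <- function(family, params, mean) {
  structure(list(family = family, params = params, mean = mean),
            class = "oa_dist")
}

#' @export
print.oa_dist <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 6),
             sep = " = ", collapse = ", ")
  cat(sprintf("<oa_dist %s (%s); mean %s>\n", x$family, p,
              paste(signif(x$mean, 6), collapse = ", ")))
  invisible(x)
}

#' Fit a Beta distribution from a mean and 95% CI
#'
#' The CI is treated as a symmetric normal-theory interval, so the standard
#' error is `(hi - lo) / 3.92`; the Beta shape parameters are then obtained by
#' moment matching. A degenerate interval (`lo == hi`) yields a point mass.
#'
#' @param mean Base-case probability.
#' @param lo,hi 95% CI bounds, `0 < lo <= mean <= hi < 1`.
#' @return An `oa_dist` with family `"beta"` (or `"fixed"` when degenerate).
#' @export
fit_beta_from_ci <- function(mean, lo, hi) {
  stopifnot(is.finite(mean), is.finite(lo), is.finite(hi))
  if (!(lo <= mean && mean <= hi))
    stop("CI bounds must bracket the mean: ", lo, " <= ", mean, " <= ", hi)
  if (mean <= 0 || mean >= 1 || lo <= 0 || hi >= 1)
    stop("mean and CI bounds must lie strictly inside (0, 1)")
  se <- (hi - lo) / 3.92
  if (se == 0) return(new_dist("fixed", list(value = mean), mean))
  v <- se^2
  if (v >= mean * (1 - mean))
    stop("CI too wide for a Beta fit: variance ", v,
         " >= mean*(1-mean) = ", mean * (1 - mean))
  alpha <- mean * (mean * (1 - mean) / v - 1)
  beta <- alpha * (1 - mean) / mean
  new_dist("beta", list(alpha = alpha, beta = beta), mean)
}

#' Fit a Gamma distribution from a mean and standard error
#'
#' Moment matching: shape = (mean/se)^2, scale = se^2/mean, so the analytic
#' mean equals the base-case value and the SD equals `se`.
#'
#' @param mean Positive base-case value (cost or utility decrement).
#' @param se Positive standard error.
#' @return An `oa_dist` with family `"gamma"`.
#' @export
fit_gamma_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(se) || se < 0) stop("se must be nonnegative")
  if (se == 0) return(new_dist("fixed", list(value = mean), mean))
  shape <- (mean / se)^2
  scale <- se^2 / mean
  new_dist("gamma", list(shape = shape, scale = scale), mean)
}

#' Dirichlet distribution from category counts
#'
#' Parameterized directly by the observed counts; optional +1 smoothing for
#' zero-count robustness. The analytic mean is `counts / sum(counts)`.
#'
#' @param counts Nonnegative counts, at least one positive.
#' @param smoothing If `TRUE`, add 1 to each count.
#' @return An `oa_dist` with family `"dirichlet"`.
#' @export
dirichlet_from_counts <- function(counts, smoothing = FALSE) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be nonnegative and finite")
  if (sum(counts) <= 0) stop("at least one count must be positive")
  alpha <- counts + if (isTRUE(smoothing)) 1 else 0
  new_dist("dirichlet", list(alpha = alpha), alpha / sum(alpha))
}

#' Mean-preserving log-normal for a hazard ratio
#'
#' Parameterized by the mean ratio and an SE on the log scale; `meanlog` is
#' chosen as `log(mean) - sdlog^2/2` so the analytic mean equals the
#' base-case ratio.
#'
#' @param mean_ratio Positive base-case ratio.
#' @param sdlog SE on the log scale.
#' @return An `oa_dist` with family `"lognormal"`.
#' @export
fit_lognormal_ratio <- function(mean_ratio, sdlog) {
  if (!is.finite(mean_ratio) || mean_ratio <= 0) stop("ratio must be positive")
  if (!is.finite(sdlog) || sdlog < 0) stop("sdlog must be nonnegative")
  if (sdlog == 0) return(new_dist("fixed", list(value = mean_ratio), mean_ratio))
  new_dist("lognormal",
           list(meanlog = log(mean_ratio) - sdlog^2 / 2, sdlog = sdlog),
           mean_ratio)
}

#' Draw from a fitted distribution
#'
#' @param dist An `oa_dist`.
#' @param n Number of draws.
#' @return For scalar families a numeric vector of length `n`; for the
#'   Dirichlet an `n x k` matrix of simplex rows.
#' @export
oa_draw <- function(dist, n = 1) {
  stopifnot(inherits(dist, "oa_dist"))
  switch(dist$family,
    fixed = rep(dist$params$value, n),
    beta = stats::rbeta(n, dist$params$alpha, dist$params$beta),
    gamma = stats::rgamma(n, shape = dist$params$shape,
                          scale = dist$params$scale),
    lognormal = stats::rlnorm(n, dist$params$meanlog, dist$params$sdlog),
    dirichlet = {
      a <- dist$params$alpha
      g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)),
                  nrow = n)
      sw <- rowSums(g)
      # all-zero rows are numerically impossible for alpha > 0 but guard anyway
      sw[sw == 0] <- 1
      g / sw
    },
    stop("unknown family: ", dist$family)
  )
}
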