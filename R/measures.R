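#' Level-1 latent residual variance of the logistic link
#'
#' In a random-intercept logistic model the individual-level residual is
#' taken from a standard logistic distribution, whose variance is pi^2/3
#' (about 3.29). It is a property of the link, not a tunable quantity.
#'
#' @format A length-one numeric constant.
#' @export
sigma2_logistic <- pi^2 / 3

check_sigma2 <- function(sigma2_u, arg = "sigma2_u") {
  if (!is.numeric(sigma2_u) || anyNA(sigma2_u)) {
    stop("`", arg, "` must be numeric and non-missing.", call. = FALSE)
  }
  if (any(sigma2_u < 0)) {
    stop("`", arg, "` must be non-negative (a variance).", call. = FALSE)
  }
  invisible(sigma2_u)
}

check_finite <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`", arg, "` must be finite and non-missing.", call. = FALSE)
  }
  invisible(x)
}

#' Intraclass correlation coefficient (latent-variable method)
#'
#' Proportion of the total latent outcome variance attributable to the
#' between-cluster variance: `sigma2_u / (sigma2_u + pi^2/3)`. For the
#' logistic link the level-1 variance is fixed at pi^2/3, so the ICC is a
#' function of the between-cluster variance alone.
#'
#' @param sigma2_u Between-cluster variance on the logit scale (>= 0).
#'   Vectorised.
#' @return Numeric vector of ICC values in `[0, 1)`.
#' @examples
#' icc(0.5)   # 0.1319
#' icc(c(0.2, 0.5, 1, 1.5))
#' @export
icc <- function(sigma2_u) {
  check_sigma2(sigma2_u)
  sigma2_u / (sigma2_u + sigma2_logistic)
}

mor_constants <- c("exact", "0.6745", "0.95")

#' Median odds ratio (MOR)
#'
#' Median of the distribution of odds ratios between two randomly chosen
#' individuals with identical covariates from different clusters, ordered so
#' the ratio is at least 1. For a normal random intercept,
#' `MOR = exp(sqrt(2 * sigma2_u) * qnorm(0.75))`.
#'
#' @inheritParams icc
#' @param constant How to evaluate the normal quantile: `"exact"` (default)
#'   uses `qnorm(0.75)` at full precision; `"0.6745"` uses the conventional
#'   rounded quantile; `"0.95"` uses the shorthand `exp(0.95 * sqrt(sigma2_u))`
#'   often quoted in applied work (the two rounded forms differ from the exact
#'   one in the third decimal).
#' @return Numeric vector of odds ratios, always >= 1; equal to 1 iff
#'   `sigma2_u == 0`.
#' @examples
#' mor(0.5)              # 1.963
#' mor(0.455, "0.95")    # 1.898
#' @export
mor <- function(sigma2_u, constant = c("exact", "0.6745", "0.95")) {
  check_sigma2(sigma2_u)
  constant <- match.arg(constant)
  switch(constant,
    "exact"  = exp(sqrt(2 * sigma2_u) * stats::qnorm(0.75)),
    "0.6745" = exp(sqrt(2 * sigma2_u) * 0.6745),
    "0.95"   = exp(0.95 * sqrt(sigma2_u))
  )
}

#' Interval odds ratio (IOR) for a cluster-level covariate
#'
#' Central interval of the distribution of odds ratios comparing two
#' individuals from clusters that differ by one unit of a cluster-level
#' covariate. With a normal random intercept the limits are
#' `exp(alpha -/+ sqrt(2 * sigma2_u) * z)` where `z` is the standard-normal
#' quantile at `(1 + interval_mass) / 2` (1.2816 for the default 80% mass).
#' The interval contains 1 exactly when the between-cluster heterogeneity
#' dominates the covariate effect.
#'
#' @param alpha Logit-scale coefficient of the cluster-level covariate.
#'   Vectorised with `sigma2_u`.
#' @inheritParams icc
#' @param interval_mass Central probability mass of the interval, in (0, 1).
#'   Default 0.80 (the conventional IOR-80).
#' @return A tibble with columns `ior_lower` and `ior_upper`. At
#'   `sigma2_u = 0` the interval degenerates to the point `exp(alpha)`.
#' @examples
#' ior(-0.3, 0.5)   # (0.2057, 2.669)
#' @export
ior <- function(alpha, sigma2_u, interval_mass = 0.80) {
  check_finite(alpha, "alpha")
  check_sigma2(sigma2_u)
  if (!is.numeric(interval_mass) || length(interval_mass) < 1 ||
      anyNA(interval_mass) || any(interval_mass <= 0) || any(interval_mass >= 1)) {
    stop("`interval_mass` must lie strictly between 0 and 1.", call. = FALSE)
  }
  z <- stats::qnorm((1 + interval_mass) / 2)
  half <- sqrt(2 * sigma2_u) * z
  tibble::tibble(
    ior_lower = exp(alpha - half),
    ior_upper = exp(alpha + half)
  )
}

#' Sorting-out index (SOI)
#'
#' Proportion of the pairwise odds ratios underlying the interval odds ratio
#' that exceed 1: `pnorm(alpha / sqrt(2 * sigma2_u))`. A value of 0.5 means
#' the cluster-level covariate is uninformative relative to the residual
#' between-cluster heterogeneity; values near 0 or 1 mean the covariate
#' dominates (negatively or positively).
#'
#' @inheritParams ior
#' @return Numeric vector of proportions in `[0, 1]`. At `sigma2_u = 0` the
#'   limiting value is returned: 1 for `alpha > 0`, 0 for `alpha < 0`, and
#'   0.5 for `alpha = 0` (fitted variances can land on the boundary, so this
#'   is a documented convention rather than an error).
#' @examples
#' soi(-0.3, 0.5)   # 0.3821
#' @export
soi <- function(alpha, sigma2_u) {
  check_finite(alpha, "alpha")
  check_sigma2(sigma2_u)
  n <- max(length(alpha), length(sigma2_u))
  alpha <- rep_len(alpha, n)
  sigma2_u <- rep_len(sigma2_u, n)
  out <- numeric(n)
  pos <- sigma2_u > 0
  out[pos] <- stats::pnorm(alpha[pos] / sqrt(2 * sigma2_u[pos]))
  out[!pos] <- 0.5 * (alpha[!pos] == 0) + 1 * (alpha[!pos] > 0)
  out
}

#' Full heterogeneity report from a variance and a cluster-covariate effect
#'
#' Bundles the four between-cluster heterogeneity measures -- ICC, MOR,
#' IOR and SOI -- computed consistently from the same between-cluster
#' variance and cluster-level covariate coefficient.
#'
#' @inheritParams ior
#' @param mor_constant Passed to [mor()] as `constant`.
#' @return A tibble (one row per input, class `"heterogeneity_report"`) with
#'   columns `alpha`, `sigma2_u`, `icc`, `mor`, `soi`, `ior_lower`,
#'   `ior_upper`, `interval_mass`, `mor_constant`.
#' @examples
#' heterogeneity_report(-0.3, 1.5)
#' @export
heterogeneity_report <- function(alpha, sigma2_u, interval_mass = 0.80,
                                 mor_constant = c("exact", "0.6745", "0.95")) {
  mor_constant <- match.arg(mor_constant)
  interval <- ior(alpha, sigma2_u, interval_mass)
  out <- tibble::tibble(
    alpha = alpha,
    sigma2_u = sigma2_u,
    icc = icc(sigma2_u),
    mor = mor(sigma2_u, mor_constant),
    soi = soi(alpha, sigma2_u),
    ior_lower = interval$ior_lower,
    ior_upper = interval$ior_upper,
    interval_mass = interval_mass,
    mor_constant = mor_constant
  )
  class(out) <- c("heterogeneity_report", class(out))
  out
}

#' Reference table of true heterogeneity measures over a variance grid
#'
#' For fixed regression coefficients and a grid of between-cluster variances,
#' tabulates the analytic (true) values of the four heterogeneity measures.
#' This is the table of true values against which simulation estimates are
#' compared.
#'
#' @param sigma2_u Vector of between-cluster variances (>= 0).
#' @param beta0,beta1,beta2 Fixed-effect coefficients (intercept and the two
#'   individual-level covariates); echoed into the table.
#' @param alpha Cluster-level covariate coefficient.
#' @inheritParams heterogeneity_report
#' @return A tibble with one row per variance and columns `sigma2_u`,
#'   `beta0`, `beta1`, `beta2`, `alpha`, `icc`, `mor`, `soi`, `ior_lower`,
#'   `ior_upper`.
#' @examples
#' true_values_table()
#' @export
true_values_table <- function(sigma2_u = c(0.2, 0.5, 1.0, 1.5),
                              beta0 = 0.5, beta1 = -1.5, beta2 = 0.3,
                              alpha = -0.3, interval_mass = 0.80,
                              mor_constant = "exact") {
  check_sigma2(sigma2_u)
  rep_ <- heterogeneity_report(alpha, sigma2_u, interval_mass, mor_constant)
  tibble::tibble(
    sigma2_u = sigma2_u,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, alpha = alpha,
    icc = rep_$icc, mor = rep_$mor, soi = rep_$soi,
    ior_lower = rep_$ior_lower, ior_upper = rep_$ior_upper
  )
}
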