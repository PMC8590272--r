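icc_band <- function(x) {
  # Band edges follow the conventional reading: below 0.50 is low, 0.50 up
  # to and including 0.75 moderate, above 0.75 up to and including 0.90
  # high, above 0.90 very high.
  dplyr::case_when(
    x < 0.50 ~ "low",
    x <= 0.75 ~ "moderate",
    x <= 0.90 ~ "high",
    TRUE ~ "very high"
  )
}

#' Qualitative interpretation of a heterogeneity report
#'
#' Annotates the four measures with the interpretation conventions of
#' multilevel epidemiology: the ICC banded as low / moderate / high / very
#' high (edges 0.50, 0.75, 0.90); the MOR read as absence (`MOR = 1`) or
#' presence of between-cluster heterogeneity; the IOR read by whether it
#' contains 1 (heterogeneity dominating the cluster-covariate effect); and
#' the SOI read relative to 0.5 (covariate uninformative) versus the tails
#' (covariate dominating).
#'
#' @param report A one-row tibble from [heterogeneity_report()] (or a fit's
#'   report from [fit_heterogeneity()]).
#' @return A tibble with columns `measure`, `value`, `label`.
#' @examples
#' interpret_heterogeneity(heterogeneity_report(0.19, 0.455))
#' @export
interpret_heterogeneity <- function(report) {
  stopifnot(is.data.frame(report), nrow(report) == 1)
  contains1 <- report$ior_lower <= 1 & report$ior_upper >= 1
  soi_label <- if (abs(report$soi - 0.5) < 0.1) {
    "near 0.5: cluster-level covariate effect is low relative to between-cluster heterogeneity"
  } else if (report$soi >= 0.9 || report$soi <= 0.1) {
    "extreme: cluster-level covariate dominates between-cluster heterogeneity"
  } else {
    "intermediate: covariate effect partially sorts clusters"
  }
  tibble::tibble(
    measure = c("icc", "mor", "ior", "soi"),
    value = c(report$icc, report$mor, NA_real_, report$soi),
    label = c(
      paste0(icc_band(report$icc), " within-cluster correlation"),
      if (report$mor == 1) "1: absence of between-cluster heterogeneity"
      else "above 1: unexplained between-cluster heterogeneity present",
      if (contains1) "contains 1: heterogeneity dominates covariate effect"
      else "excludes 1: covariate effect exceeds between-cluster heterogeneity",
      soi_label
    )
  )
}

#' Analyse a clustered binary dataset end to end
#'
#' The application workflow: fit the unadjusted model (intercept plus
#' random effect only) to quantify raw between-cluster heterogeneity via
#' ICC and MOR, then fit the covariate-adjusted model and report all four
#' measures with their qualitative interpretation.
#'
#' @param data A clustered dataset tibble (schema of
#'   [simulate_clustered()]) or a path to a CSV in that schema.
#' @inheritParams fit_ri_logit
#' @inheritParams heterogeneity_report
#' @return A list of class `"clustered_analysis"` with elements
#'   `unadjusted` (list: `fit`, `icc`, `mor`), `adjusted` (list: `fit`,
#'   `report`, `interpretation`).
#' @examples
#' d <- simulate_application(seed = 1, n_clusters = 200)
#' analyze_clustered(d, n_quad = 7)
#' @export
analyze_clustered <- function(data, n_quad = 15, interval_mass = 0.80,
                              mor_constant = c("exact", "0.6745", "0.95")) {
  mor_constant <- match.arg(mor_constant)
  if (is.character(data)) data <- read_clustered(data)
  fit0 <- fit_ri_logit(data, n_quad = n_quad, covariates = FALSE)
  fit1 <- fit_ri_logit(data, n_quad = n_quad, covariates = TRUE)
  report <- heterogeneity_report(fit1$alpha, fit1$sigma2_u,
                                 interval_mass = interval_mass,
                                 mor_constant = mor_constant)
  out <- list(
    unadjusted = list(
      fit = fit0,
      icc = icc(fit0$sigma2_u),
      mor = mor(fit0$sigma2_u, mor_constant)
    ),
    adjusted = list(
      fit = fit1,
      report = report,
      interpretation = interpret_heterogeneity(report)
    )
  )
  class(out) <- "clustered_analysis"
  out
}

#' @export
print.clustered_analysis <- function(x, digits = 3, ...) {
  cat("Two-level logistic regression heterogeneity analysis\n")
  cat(sprintf("  %d observations in %d clusters\n",
              x$adjusted$fit$n_obs, x$adjusted$fit$n_clusters))
  cat(sprintf("Unadjusted model: sigma2_u = %.*f, ICC = %.*f, MOR = %.*f\n",
              digits, x$unadjusted$fit$sigma2_u,
              digits, x$unadjusted$icc, digits, x$unadjusted$mor))
  r <- x$adjusted$report
  cat(sprintf("Adjusted model:   sigma2_u = %.*f, alpha = %.*f\n",
              digits, r$sigma2_u, digits, r$alpha))
  cat(sprintf("  ICC = %.*f, MOR = %.*f, SOI = %.*f, IOR-%d%% = (%.*f, %.*f)\n",
              digits, r$icc, digits, r$mor, digits, r$soi,
              round(100 * r$interval_mass), digits, r$ior_lower,
              digits, r$ior_upper))
  for (i in seq_len(nrow(x$adjusted$interpretation))) {
    cat(sprintf("  %-4s %s\n", x$adjusted$interpretation$measure[i],
                x$adjusted$interpretation$label[i]))
  }
  invisible(x)
}
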