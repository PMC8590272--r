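#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted random-intercept logistic model
#'
#' @param x An `"ri_logit"` object from [fit_ri_logit()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (fixed effects plus
#'   `sigma_u`) and columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald; `NA` for `sigma_u`, whose null lies on the boundary).
#' @method tidy ri_logit
#' @export
tidy.ri_logit <- function(x, ...) {
  terms <- c(names(x$coefficients), "sigma_u")
  est <- c(unname(x$coefficients), x$sigma_u)
  se <- unname(x$std_errors[terms])
  stat <- est / se
  p <- 2 * stats::pnorm(-abs(stat))
  is_sigma <- terms == "sigma_u"
  stat[is_sigma] <- NA_real_
  p[is_sigma] <- NA_real_
  tibble::tibble(term = terms, estimate = est, std.error = se,
                 statistic = stat, p.value = p)
}

#' One-row model summary of a fitted random-intercept logistic model
#'
#' @inheritParams tidy.ri_logit
#' @return A one-row tibble with `logLik`, `sigma2_u`, `converged`,
#'   `boundary`, `n_clusters`, `nobs`, `n_quad`.
#' @method glance ri_logit
#' @export
glance.ri_logit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    sigma2_u = x$sigma2_u,
    converged = x$converged,
    boundary = x$boundary,
    n_clusters = x$n_clusters,
    nobs = x$n_obs,
    n_quad = x$n_quad
  )
}

#' @export
print.ri_logit <- function(x, digits = 4, ...) {
  cat("Random-intercept logistic regression (adaptive Gauss-Hermite,",
      x$n_quad, "nodes)\n")
  cat(sprintf("  %d observations in %d clusters; logLik = %.3f%s\n",
              x$n_obs, x$n_clusters, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, digits))
  cat(sprintf("  sigma2_u = %.*f%s\n", digits, x$sigma2_u,
              if (x$boundary) " (boundary: variance estimated at zero)" else ""))
  invisible(x)
}
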