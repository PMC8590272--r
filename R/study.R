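#' Root mean square error of a vector of estimates
#'
#' `sqrt(mean((estimates - true_value)^2))` across simulation replicates:
#' the accuracy summary used throughout the Monte-Carlo study.
#'
#' @param estimates Non-empty numeric vector of replicate estimates.
#' @param true_value The true (analytic) value of the quantity.
#' @return A single non-negative number.
#' @examples
#' rmse(c(0.2, 0.4), 0.3)  # 0.1
#' @export
rmse <- function(estimates, true_value) {
  if (length(estimates) == 0) stop("`estimates` must be non-empty.", call. = FALSE)
  check_finite(estimates, "estimates")
  check_finite(true_value, "true_value")
  sqrt(mean((estimates - true_value)^2))
}

study_quantities <- c("beta0", "beta1", "beta2", "alpha",
                      "icc", "mor", "soi", "ior_lower", "ior_upper")

#' Simulate, fit and summarise one grid condition
#'
#' Simulates `n_reps` datasets at one (clusters, cluster size, variance)
#' condition, fits each with the adaptive Gauss-Hermite maximum-likelihood
#' fitter, computes the four heterogeneity measures from each fit, and
#' aggregates mean estimates and RMSEs against the analytic true values.
#' Means and RMSEs are taken over converged fits only; non-converged or
#' failed fits are counted, never silently dropped.
#'
#' @param n_clusters,cluster_size,sigma2_u The condition.
#' @param n_reps Number of replicate datasets.
#' @param base_seed Integer base seed; replicate `r` uses
#'   [replicate_seed()]`(base_seed, condition_index, r)`.
#' @param condition_index Zero-based index used in the seed derivation
#'   (supplied by [run_grid()]; leave 0 for standalone runs).
#' @param beta0,beta1,beta2,alpha True fixed effects of the generating
#'   model.
#' @param n_quad Quadrature nodes for the fitter.
#' @return A tibble with one row per quantity (`beta0`, `beta1`, `beta2`,
#'   `alpha`, `icc`, `mor`, `soi`, `ior_lower`, `ior_upper`) and columns
#'   `n_clusters`, `cluster_size`, `sigma2_u`, `quantity`, `truth`, `mean`,
#'   `rmse`, `n_converged`, `n_failed`.
#' @examples
#' run_condition(10, 5, 0.5, n_reps = 2, base_seed = 1, n_quad = 5)
#' @export
run_condition <- function(n_clusters, cluster_size, sigma2_u, n_reps,
                          base_seed = 1, condition_index = 0,
                          beta0 = 0.5, beta1 = -1.5, beta2 = 0.3,
                          alpha = -0.3, n_quad = 15) {
  stopifnot(n_reps >= 1)
  ests <- purrr::map(seq_len(n_reps), function(r) {
    d <- simulate_clustered(n_clusters, cluster_size, sigma2_u,
                            beta0, beta1, beta2, alpha,
                            seed = replicate_seed(base_seed, condition_index, r))
    fit <- tryCatch(fit_ri_logit(d, n_quad = n_quad), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    rep_ <- heterogeneity_report(fit$alpha, fit$sigma2_u)
    tibble::tibble(
      beta0 = fit$coefficients[["(Intercept)"]],
      beta1 = fit$coefficients[["x1"]],
      beta2 = fit$coefficients[["x2"]],
      alpha = fit$alpha,
      icc = rep_$icc, mor = rep_$mor, soi = rep_$soi,
      ior_lower = rep_$ior_lower, ior_upper = rep_$ior_upper
    )
  })
  ok <- !purrr::map_lgl(ests, is.null)
  est_tbl <- dplyr::bind_rows(ests[ok])
  truth_rep <- heterogeneity_report(alpha, sigma2_u)
  truth <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, alpha = alpha,
             icc = truth_rep$icc, mor = truth_rep$mor, soi = truth_rep$soi,
             ior_lower = truth_rep$ior_lower, ior_upper = truth_rep$ior_upper)
  out <- tibble::tibble(
    n_clusters = n_clusters,
    cluster_size = cluster_size,
    sigma2_u = sigma2_u,
    quantity = study_quantities,
    truth = unname(truth[study_quantities]),
    mean = NA_real_,
    rmse = NA_real_,
    n_converged = sum(ok),
    n_failed = n_reps - sum(ok)
  )
  if (sum(ok) > 0) {
    out$mean <- purrr::map_dbl(study_quantities, ~ mean(est_tbl[[.x]]))
    out$rmse <- purrr::map_dbl(study_quantities,
                               ~ rmse(est_tbl[[.x]], truth[[.x]]))
  }
  out
}

#' Run the full factorial simulation study
#'
#' Crosses cluster counts, cluster sizes and random-effect variances, runs
#' [run_condition()] on every cell, and binds the summaries. Seeds are
#' derived from the condition's position in the grid, so the result is
#' independent of execution order and any single cell can be reproduced in
#' isolation.
#'
#' @param cluster_counts,cluster_sizes,variances Grid axes. The reference
#'   study design uses counts (10, 50, 100, 300, 500), sizes
#'   (5, 20, 50, 100, 250) and variances (0.2, 0.5, 1.0, 1.5).
#' @param n_reps Replicates per cell (the reference design uses 1000; a
#'   desk-scale profile of about 100 is adequate for trend checks).
#' @inheritParams run_condition
#' @return A tibble of class `"hetlogit_study"`: the row-bound
#'   [run_condition()] summaries.
#' @examples
#' run_grid(c(10, 20), 5, 0.5, n_reps = 2, base_seed = 1, n_quad = 5)
#' @export
run_grid <- function(cluster_counts, cluster_sizes, variances, n_reps,
                     base_seed = 1, beta0 = 0.5, beta1 = -1.5, beta2 = 0.3,
                     alpha = -0.3, n_quad = 15) {
  stopifnot(length(cluster_counts) >= 1, length(cluster_sizes) >= 1,
            length(variances) >= 1, n_reps >= 1)
  grid <- tidyr::expand_grid(
    sigma2_u = variances,
    n_clusters = cluster_counts,
    cluster_size = cluster_sizes
  )
  out <- purrr::pmap(
    list(grid$n_clusters, grid$cluster_size, grid$sigma2_u,
         seq_len(nrow(grid)) - 1),
    function(H, N, s2, idx) {
      run_condition(H, N, s2, n_reps = n_reps, base_seed = base_seed,
                    condition_index = idx, beta0 = beta0, beta1 = beta1,
                    beta2 = beta2, alpha = alpha, n_quad = n_quad)
    }
  )
  out <- dplyr::bind_rows(out)
  class(out) <- c("hetlogit_study", class(out))
  out
}

#' Render study summaries as wide, paper-style tables
#'
#' Pivots the long study summary into tables with one row per
#' (clusters, cluster size) condition and one column per quantity, split by
#' random-effect variance: `style = "estimates"` tabulates mean estimates,
#' `style = "rmse"` tabulates RMSEs, and `style = "true"` returns the
#' analytic true-value table for the variances present.
#'
#' @param summaries A `"hetlogit_study"` tibble from [run_grid()] (or
#'   row-bound [run_condition()] output).
#' @param style One of `"rmse"`, `"estimates"`, `"true"`.
#' @param digits Decimal places used when rounding rendered values
#'   (default 4).
#' @return For `"true"` a single tibble; otherwise a named list of tibbles,
#'   one per variance (names `"sigma2_<value>"`).
#' @export
render_tables <- function(summaries, style = c("rmse", "estimates", "true"),
                          digits = 4) {
  style <- match.arg(style)
  if (style == "true") {
    s2 <- sort(unique(summaries$sigma2_u))
    out <- true_values_table(sigma2_u = s2)
    out[-1] <- lapply(out[-1], round, digits = digits)
    return(out)
  }
  value <- if (style == "rmse") "rmse" else "mean"
  split_s2 <- split(summaries, summaries$sigma2_u)
  out <- purrr::map(split_s2, function(block) {
    wide <- tidyr::pivot_wider(
      dplyr::select(block, dplyr::all_of(c(
        "n_clusters", "cluster_size", "quantity", value, "n_converged",
        "n_failed"))),
      names_from = "quantity", values_from = dplyr::all_of(value)
    )
    wide <- dplyr::relocate(wide, dplyr::all_of(study_quantities),
                            .after = "cluster_size")
    wide[study_quantities] <- lapply(wide[study_quantities], round,
                                     digits = digits)
    dplyr::arrange(wide, .data$n_clusters, .data$cluster_size)
  })
  names(out) <- paste0("sigma2_", names(split_s2))
  out
}

#' Write study tables to CSV files
#'
#' Writes `true_values.csv` plus `estimates_<sigma2>.csv` and
#' `rmse_<sigma2>.csv` per variance into `dir`. Output is deterministic:
#' identical summaries produce byte-identical files.
#'
#' @inheritParams render_tables
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_tables <- function(summaries, dir, digits = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  truth <- render_tables(summaries, "true", digits = digits)
  f <- file.path(dir, "true_values.csv")
  readr::write_csv(truth, f)
  files <- c(files, f)
  for (style in c("estimates", "rmse")) {
    tabs <- render_tables(summaries, style, digits = digits)
    for (nm in names(tabs)) {
      f <- file.path(dir, paste0(style, "_", sub("^sigma2_", "", nm), ".csv"))
      readr::write_csv(tabs[[nm]], f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
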