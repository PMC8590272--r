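# Adaptive Gauss-Hermite machinery for the random-intercept logistic model.
#
# The per-cluster marginal likelihood is
#   L_h = \int prod_i Bernoulli(y_hi | plogis(x_hi' beta + u)) phi(u; 0, sigma2) du
# approximated by Gauss-Hermite quadrature centred and scaled at the
# conditional mode of u given the data (adaptive GH); one node recovers the
# Laplace approximation, and sigma = 0 collapses to the ordinary logistic
# log-likelihood exactly.

.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- if (n == 1) {
      list(x = 0, w = sqrt(pi))  # one node: the Laplace approximation
    } else {
      pracma::gaussHermite(n)
    }
  }
  .gh_cache[[key]]
}

# Validate and convert a clustered dataset into the internal fitting layout.
# covariates = FALSE keeps only the intercept column (the "unadjusted" model).
prepare_cluster_data <- function(data, covariates = TRUE) {
  required <- c("cluster_id", "x1", "x2", "xh", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("Dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !data$y %in% c(0, 1)
  if (any(bad)) {
    stop("Column `y` must be binary 0/1; offending rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  cl <- match(data$cluster_id, unique(data$cluster_id))
  H <- max(cl)
  if (any(tapply(data$xh, cl, function(v) length(unique(v))) > 1)) {
    stop("`xh` must be constant within each cluster.", call. = FALSE)
  }
  # Order rows by cluster so per-cluster sums reduce to segment sums; the
  # marginal likelihood is invariant to row order within clusters.
  ord <- order(cl)
  data <- data[ord, ]
  cl <- cl[ord]
  X <- if (covariates) {
    cbind(`(Intercept)` = 1, x1 = data$x1, x2 = data$x2, xh = data$xh)
  } else {
    cbind(`(Intercept)` = rep(1, nrow(data)))
  }
  sizes <- tabulate(cl, H)
  if (any(sizes == 0)) stop("Empty cluster.", call. = FALSE)
  ends <- cumsum(sizes)
  list(X = X, y = as.numeric(data$y), cl = cl, H = H, n = nrow(data),
       ends = ends)
}

# Per-cluster segment sums of a vector (rows already ordered by cluster).
seg_sum <- function(x, ends) {
  cs <- cumsum(x)
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

# Column-wise segment sums of a matrix: returns an H x Q matrix.
seg_sum_mat <- function(m, ends) {
  cs <- apply(m, 2, cumsum)
  if (length(ends) == 1) return(matrix(cs[ends, ], nrow = 1))
  cs[ends, , drop = FALSE] - rbind(0, cs[ends[-length(ends)], , drop = FALSE])
}

# Find the conditional mode of u_h per cluster by damped Newton iterations.
# The per-cluster objective (Bernoulli log-likelihood plus Gaussian log
# prior) is strictly concave in u, so Newton with a step cap converges;
# returns the mode and the curvature W_h = sum_i p(1-p) at the mode.
find_modes <- function(eta_fix, y, cl, ends, sigma2, u_start, tol = 1e-9,
                       max_iter = 100) {
  plogis <- stats::plogis
  u <- u_start
  for (iter in seq_len(max_iter)) {
    eta <- eta_fix + u[cl]
    p <- plogis(eta)
    g <- seg_sum(y - p, ends) - u / sigma2
    W <- seg_sum(p * (1 - p), ends)
    du <- g / (W + 1 / sigma2)
    du[!is.finite(du)] <- 0
    du <- pmin(pmax(du, -4), 4)  # step cap guards rare early overshoot
    u <- pmin(pmax(u + du, -1e3), 1e3)
    if (max(abs(du)) < tol) break
  }
  eta <- eta_fix + u[cl]
  p <- plogis(eta)
  list(u = u, W = seg_sum(p * (1 - p), ends))
}

# Core evaluator used by both the exported marginal_loglik and the fitter.
# `state` (optional environment) carries warm-start modes between calls.
agq_loglik_core <- function(prep, beta, sigma_u, n_quad, state = NULL) {
  plogis <- stats::plogis
  eta_fix <- drop(prep$X %*% beta)
  sgn <- 2 * prep$y - 1
  if (sigma_u < 1e-10) {
    return(sum(plogis(sgn * eta_fix, log.p = TRUE)))
  }
  sigma2 <- sigma_u^2
  u_start <- if (!is.null(state) && !is.null(state$u) &&
                 length(state$u) == prep$H) state$u else numeric(prep$H)
  modes <- find_modes(eta_fix, prep$y, prep$cl, prep$ends, sigma2, u_start)
  if (!is.null(state)) state$u <- modes$u
  s <- 1 / sqrt(modes$W + 1 / sigma2)
  gh <- gauss_hermite(n_quad)
  # All nodes at once: Z is H x Q, eta_mat expands to rows, one segment-sum
  # pass per column.
  Z <- modes$u + sqrt(2) * s %o% gh$x
  eta_mat <- eta_fix + Z[prep$cl, , drop = FALSE]
  lp <- plogis(sgn * eta_mat, log.p = TRUE)
  a <- seg_sum_mat(lp, prep$ends) +
    stats::dnorm(Z, 0, sigma_u, log = TRUE) +
    rep(gh$x^2 + log(gh$w), each = prep$H) +
    log(sqrt(2) * s)
  mx <- a[, 1]
  for (j in seq_len(n_quad)[-1]) mx <- pmax(mx, a[, j])
  sum(mx + log(rowSums(exp(a - mx))))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates, by adaptive Gauss-Hermite quadrature, the log-likelihood of a
#' two-level logistic regression with a normal random intercept: the sum
#' over clusters of the log of the Bernoulli likelihood integrated against
#' `Normal(0, sigma_u^2)`. Quadrature nodes are centred and scaled at each
#' cluster's conditional mode. At `sigma_u = 0` the integral collapses and
#' the value equals the ordinary logistic log-likelihood exactly.
#'
#' @param data A clustered dataset with columns `cluster_id`, `x1`, `x2`,
#'   `xh`, `y` (see [simulate_clustered()]).
#' @param beta Length-3 vector of coefficients for the intercept, `x1`
#'   and `x2`.
#' @param alpha Coefficient of the cluster-level covariate `xh`.
#' @param sigma_u Random-intercept standard deviation (>= 0).
#' @param n_quad Number of quadrature nodes (1 gives the Laplace
#'   approximation).
#' @return The marginal log-likelihood (a single number).
#' @examples
#' d <- simulate_clustered(5, 4, 0.5, seed = 1)
#' marginal_loglik(d, beta = c(0.5, -1.5, 0.3), alpha = -0.3, sigma_u = sqrt(0.5))
#' @export
marginal_loglik <- function(data, beta, alpha, sigma_u, n_quad = 15) {
  if (length(beta) != 3) stop("`beta` must have length 3.", call. = FALSE)
  check_finite(beta, "beta"); check_finite(alpha, "alpha")
  if (!is.finite(sigma_u) || sigma_u < 0) {
    stop("`sigma_u` must be finite and >= 0.", call. = FALSE)
  }
  prep <- prepare_cluster_data(data)
  agq_loglik_core(prep, c(beta, alpha), sigma_u, n_quad)
}

#' Fit a random-intercept logistic regression by maximum likelihood
#'
#' Maximises the adaptive Gauss-Hermite marginal likelihood over the fixed
#' effects and the random-intercept standard deviation. The optimisation is
#' on `sigma_u` over the half-line with explicit boundary handling, so a
#' zero variance estimate is attainable and flagged; initialisation is
#' deterministic (ordinary logistic fit, `sigma_u` started at 0.3), so
#' fits are reproducible without random restarts.
#'
#' @inheritParams marginal_loglik
#' @param covariates If `FALSE`, fit the "unadjusted" model with only an
#'   intercept and the random effect (no covariates), the form used to
#'   quantify raw between-cluster heterogeneity.
#' @param max_iter Iteration cap passed to the L-BFGS-B optimiser.
#' @param grad_tol Largest absolute score at the optimum still declared
#'   converged.
#' @return An object of class `"ri_logit"`: a list with elements
#'   `coefficients` (named fixed effects), `alpha` (the `xh` coefficient or
#'   `NA` for the unadjusted model), `sigma2_u`, `sigma_u`, `std_errors`
#'   (named; `NA` for `sigma_u` at the boundary), `loglik`, `converged`,
#'   `boundary`, `n_clusters`, `n_obs`, `n_quad`. Use [tidy()] and
#'   [glance()] to extract tibbles.
#' @examples
#' d <- simulate_clustered(30, 10, 0.5, seed = 7)
#' fit <- fit_ri_logit(d, n_quad = 7)
#' glance(fit)
#' @export
fit_ri_logit <- function(data, n_quad = 15, covariates = TRUE,
                         max_iter = 500, grad_tol = 0.05) {
  prep <- prepare_cluster_data(data, covariates = covariates)
  if (prep$H < 2) stop("Need at least 2 clusters.", call. = FALSE)
  if (all(prep$y == 0) || all(prep$y == 1)) {
    stop("Outcome is constant; the intercept is unidentifiable.",
         call. = FALSE)
  }
  p <- ncol(prep$X)
  glm0 <- suppressWarnings(
    stats::glm.fit(prep$X, prep$y, family = stats::binomial())
  )
  start <- c(glm0$coefficients, 0.3)
  start[!is.finite(start)] <- 0  # rank-deficient designs give NA glm coefs
  state <- new.env(parent = emptyenv())
  negll <- function(theta) {
    val <- -agq_loglik_core(prep, theta[seq_len(p)], theta[p + 1], n_quad,
                            state)
    if (!is.finite(val)) .Machine$double.xmax / 2 else val
  }
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), 0),
                      upper = c(rep(Inf, p), 50),
                      control = list(maxit = max_iter))
  theta <- unname(opt$par)
  sigma_u <- theta[p + 1]
  boundary <- sigma_u < 1e-4
  if (boundary) {
    # At the boundary the MLE of beta is the ordinary logistic fit.
    refit <- stats::glm.fit(prep$X, prep$y, family = stats::binomial())
    theta <- c(refit$coefficients, 0)
    sigma_u <- 0
    loglik <- agq_loglik_core(prep, theta[seq_len(p)], 0, n_quad)
  } else {
    loglik <- -opt$value
  }
  grad <- num_gradient(negll, theta, boundary = boundary, p = p)
  converged <- opt$convergence == 0 && max(abs(grad)) < grad_tol * (1 + abs(loglik))
  if (any(!is.finite(theta[seq_len(p)])) ||
      max(abs(theta[seq_len(p)]), na.rm = TRUE) > 30) {
    warning("Fixed-effect estimates diverged; the design may be completely ",
            "separated.", call. = FALSE)
    converged <- FALSE
  }
  se <- rep(NA_real_, p + 1)
  if (boundary) {
    eta <- drop(prep$X %*% theta[seq_len(p)])
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    info <- crossprod(prep$X * w, prep$X)
    se[seq_len(p)] <- sqrt(diag(solve(info)))
  } else {
    hess <- try(stats::optimHess(theta, negll), silent = TRUE)
    if (!inherits(hess, "try-error")) {
      cov <- try(solve(hess), silent = TRUE)
      if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
        se <- sqrt(diag(cov))
      }
    }
  }
  coefs <- theta[seq_len(p)]
  names(coefs) <- colnames(prep$X)
  names(se) <- c(colnames(prep$X), "sigma_u")
  out <- list(
    coefficients = coefs,
    alpha = if (covariates) unname(coefs["xh"]) else NA_real_,
    sigma_u = sigma_u,
    sigma2_u = sigma_u^2,
    std_errors = se,
    loglik = loglik,
    converged = converged,
    boundary = boundary,
    n_clusters = prep$H,
    n_obs = prep$n,
    n_quad = n_quad
  )
  class(out) <- "ri_logit"
  out
}

# Central-difference gradient; at the boundary the sigma component is the
# one-sided directional derivative into the feasible region (clamped at 0
# when it points outward, i.e. when the boundary is the optimum).
num_gradient <- function(fn, theta, boundary = FALSE, p = length(theta) - 1,
                         h = 1e-5) {
  g <- numeric(length(theta))
  f0 <- fn(theta)
  for (k in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h
    if (k == p + 1 && boundary) {
      g[k] <- min(0, -(fn(tp) - f0) / h)  # score direction, feasible side
      next
    }
    tm[k] <- tm[k] - h
    g[k] <- -(fn(tp) - fn(tm)) / (2 * h)
  }
  g
}

#' Fit a clustered dataset and report its heterogeneity measures
#'
#' Convenience composition: fit the random-intercept logistic model, then
#' compute the ICC, MOR, IOR and SOI from the estimated variance and
#' cluster-covariate coefficient. When the variance estimate is on the
#' boundary the measures use the zero-variance conventions (ICC 0, MOR 1,
#' degenerate IOR, limiting SOI).
#'
#' @inheritParams fit_ri_logit
#' @inheritParams heterogeneity_report
#' @return A list with elements `fit` (an `"ri_logit"` object) and `report`
#'   (a one-row [heterogeneity_report()] tibble).
#' @examples
#' d <- simulate_clustered(30, 10, 0.5, seed = 7)
#' fit_heterogeneity(d, n_quad = 7)$report
#' @export
fit_heterogeneity <- function(data, n_quad = 15, interval_mass = 0.80,
                              mor_constant = "exact", ...) {
  fit <- fit_ri_logit(data, n_quad = n_quad, ...)
  if (!is.finite(fit$alpha)) {
    stop("The IOR and SOI need a cluster-level covariate; fit with ",
         "`covariates = TRUE`.", call. = FALSE)
  }
  report <- heterogeneity_report(fit$alpha, fit$sigma2_u,
                                 interval_mass = interval_mass,
                                 mor_constant = mor_constant)
  list(fit = fit, report = report)
}
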