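# Independent oracles used across the suite. These re-derive the quantities
# the package computes through different routes (root-finding on the normal
# CDF, dense-grid integration, exhaustive search) and must stay independent
# of the implementation paths they check.

# Standard-normal quantile by bisection on pnorm (no qnorm).
oracle_qnorm <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-40, 40),
                 tol = .Machine$double.eps^0.75)$root
}

# The four measures evaluated directly from their defining expressions,
# using only pnorm and the root-finding quantile above.
oracle_measures <- function(alpha, sigma2_u, interval_mass = 0.80) {
  sd2 <- sqrt(2 * sigma2_u)
  z_hi <- oracle_qnorm((1 + interval_mass) / 2)
  list(
    icc = sigma2_u / (sigma2_u + pi^2 / 3),
    mor = exp(sd2 * oracle_qnorm(0.75)),
    soi = if (sigma2_u > 0) stats::pnorm(alpha / sd2) else
      0.5 * (alpha == 0) + (alpha > 0),
    ior_lower = exp(alpha - sd2 * z_hi),
    ior_upper = exp(alpha + sd2 * z_hi)
  )
}

# Brute-force marginal log-likelihood by dense trapezoid integration of the
# integrand over u in [-10 sigma, 10 sigma].
oracle_marginal_loglik <- function(data, beta, alpha, sigma_u,
                                   n_grid = 20001) {
  u <- seq(-10 * sigma_u, 10 * sigma_u, length.out = n_grid)
  du <- u[2] - u[1]
  eta_fix <- beta[1] + beta[2] * data$x1 + beta[3] * data$x2 + alpha * data$xh
  total <- 0
  for (h in unique(data$cluster_id)) {
    rows <- which(data$cluster_id == h)
    log_f <- vapply(u, function(uu) {
      eta <- eta_fix[rows] + uu
      sum(stats::plogis((2 * data$y[rows] - 1) * eta, log.p = TRUE))
    }, numeric(1))
    integrand <- exp(log_f) * stats::dnorm(u, 0, sigma_u)
    total <- total + log(sum((integrand[-1] + integrand[-n_grid]) / 2) * du)
  }
  total
}

# Exhaustive-search maximiser: a coarse lattice around `centre` refined by
# repeatedly shrinking the grid about the incumbent best point. Exercises
# the optimiser through a route that shares only the likelihood evaluator.
oracle_grid_argmax <- function(data, centre, half_width = 1.5, n_rounds = 6,
                               n_points = 5, n_quad = 15) {
  best <- centre
  width <- rep(half_width, length(centre))
  for (round in seq_len(n_rounds)) {
    axes <- lapply(seq_along(best), function(k) {
      v <- seq(best[k] - width[k], best[k] + width[k], length.out = n_points)
      if (k == length(best)) v[v >= 0] else v  # sigma stays on the half-line
    })
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, function(th) {
      marginal_loglik(data, th[1:3], th[4], th[5], n_quad = n_quad)
    })
    best <- grid[which.max(vals), ]
    width <- width * 2 / (n_points - 1)  # new grid nests the old spacing
  }
  unname(best)
}

# Small random clustered dataset for oracle comparisons.
tiny_dataset <- function(n_clusters, cluster_size, seed) {
  simulate_clustered(n_clusters, cluster_size, sigma2_u = 0.4,
                     beta0 = 0.3, beta1 = -0.8, beta2 = 0.2, alpha = -0.2,
                     seed = seed)
}
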