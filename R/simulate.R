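#' Draw cluster random effects
#'
#' Draws `n_clusters` independent random intercepts from
#' `Normal(0, sigma2_u)` using the current R random number stream (or a
#' local seed when `seed` is supplied).
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param sigma2_u Random-effect variance (>= 0); `0` gives a vector of
#'   exact zeros.
#' @param seed Optional integer seed applied locally (the global RNG state
#'   is restored afterwards).
#' @return Numeric vector of length `n_clusters`.
#' @export
draw_random_effects <- function(n_clusters, sigma2_u, seed = NULL) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1 || n_clusters < 1) {
    stop("`n_clusters` must be a single integer >= 1.", call. = FALSE)
  }
  check_sigma2(sigma2_u)
  if (!is.null(seed)) {
    return(with_local_seed(seed, stats::rnorm(n_clusters, 0, sqrt(sigma2_u))))
  }
  stats::rnorm(n_clusters, 0, sqrt(sigma2_u))
}

# Run `expr` under `set.seed(seed)` while preserving the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Inverse logit
#'
#' Maps a linear predictor to a probability, `1 / (1 + exp(-eta))`.
#'
#' @param eta Numeric vector of logit-scale values.
#' @return Probabilities in (0, 1).
#' @export
inv_logit <- function(eta) stats::plogis(eta)

# Shared core: simulate one two-level binary dataset given per-cluster sizes.
simulate_core <- function(cluster_sizes, sigma2_u, beta0, beta1, beta2, alpha,
                          cluster_covariate_prob, keep_prob) {
  n_clusters <- length(cluster_sizes)
  u <- stats::rnorm(n_clusters, 0, sqrt(sigma2_u))
  xh_cl <- stats::rbinom(n_clusters, 1L, cluster_covariate_prob)
  cl <- rep.int(seq_len(n_clusters), cluster_sizes)
  n <- length(cl)
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  eta <- beta0 + beta1 * x1 + beta2 * x2 + alpha * xh_cl[cl] + u[cl]
  prob <- stats::plogis(eta)
  y <- stats::rbinom(n, 1L, prob)
  out <- tibble::tibble(
    cluster_id = cl,
    x1 = x1, x2 = x2,
    xh = xh_cl[cl],
    y = y,
    u_h = u[cl]
  )
  if (keep_prob) out$prob <- prob
  out
}

#' Simulate a two-level clustered binary dataset
#'
#' Generates data from the random-intercept logistic model
#' `logit(pi_hi) = beta0 + beta1*x1 + beta2*x2 + alpha*xh + u_h` with
#' `u_h ~ N(0, sigma2_u)`, `x1, x2 ~ N(0, 1)` fresh per individual, and a
#' binary cluster-level covariate `xh ~ Bernoulli(cluster_covariate_prob)`
#' drawn once per cluster and held constant within it. The true random
#' effect is retained in the `u_h` column.
#'
#' @param n_clusters Number of clusters H (>= 1).
#' @param cluster_size Individuals per cluster (constant across clusters).
#' @param sigma2_u Random-intercept variance (>= 0).
#' @param beta0,beta1,beta2,alpha Logit-scale coefficients; the defaults are
#'   the reference condition used throughout the package's simulation study.
#' @param cluster_covariate_prob Success probability of the cluster-level
#'   Bernoulli covariate (default 0.5).
#' @param seed Optional integer seed (applied locally).
#' @param keep_prob If `TRUE`, retain the per-row success probability in a
#'   `prob` column (debugging aid; lets `u_h` be reconstructed exactly as
#'   `qlogis(prob)` minus the fixed part).
#' @return A tibble with columns `cluster_id`, `x1`, `x2`, `xh`, `y`, `u_h`
#'   (and `prob` when requested), one row per individual.
#' @examples
#' d <- simulate_clustered(10, 5, 0.5, seed = 1)
#' dplyr::count(d, cluster_id)
#' @export
simulate_clustered <- function(n_clusters, cluster_size, sigma2_u,
                               beta0 = 0.5, beta1 = -1.5, beta2 = 0.3,
                               alpha = -0.3, cluster_covariate_prob = 0.5,
                               seed = NULL, keep_prob = FALSE) {
  stopifnot(length(n_clusters) == 1, n_clusters >= 1,
            length(cluster_size) == 1, cluster_size >= 1)
  check_sigma2(sigma2_u)
  for (nm in c("beta0", "beta1", "beta2", "alpha")) check_finite(get(nm), nm)
  if (cluster_covariate_prob < 0 || cluster_covariate_prob > 1) {
    stop("`cluster_covariate_prob` must be in [0, 1].", call. = FALSE)
  }
  sim <- function() {
    simulate_core(rep.int(as.integer(cluster_size), n_clusters), sigma2_u,
                  beta0, beta1, beta2, alpha, cluster_covariate_prob, keep_prob)
  }
  if (!is.null(seed)) with_local_seed(seed, sim()) else sim()
}

# Solve the intercept so the marginal outcome prevalence matches `target`,
# integrating over the normal random effect (Gauss-Hermite) and the binary
# cluster covariate.
solve_intercept_for_prevalence <- function(target, sigma2_u, alpha,
                                           cluster_covariate_prob, n_quad = 40) {
  gh <- gauss_hermite(n_quad)
  u <- sqrt(2 * sigma2_u) * gh$x
  w <- gh$w / sqrt(pi)
  prev <- function(b0) {
    p1 <- sum(w * stats::plogis(b0 + alpha + u))
    p0 <- sum(w * stats::plogis(b0 + u))
    cluster_covariate_prob * p1 + (1 - cluster_covariate_prob) * p0 - target
  }
  stats::uniroot(prev, c(-10, 10), tol = 1e-10)$root
}

#' Simulate a dataset with the structure of a community household survey
#'
#' Structural emulator of a two-level childhood-anemia analysis: about 850
#' communities with 1 to 15 children each (mean about 5.5, truncated
#' Poisson sizes), a binary community-level covariate (a rural/urban
#' analogue with rural odds ratio `exp(alpha)`), between-community variance
#' 0.455 on the logit scale, and an intercept calibrated so the marginal
#' outcome prevalence is about 0.63. Individual covariates `x1`, `x2` are
#' carried with zero true coefficients: the preset emulates the data
#' *structure*, not the survey's substantive covariates.
#'
#' @param seed Optional integer seed (applied locally).
#' @param n_clusters Number of communities.
#' @param mean_size Mean of the (untruncated) Poisson cluster-size law.
#' @param size_range Inclusive truncation bounds for cluster sizes.
#' @param sigma2_u Between-community variance.
#' @param alpha Logit coefficient of the community covariate (default
#'   `log(1.21)`, a rural odds ratio of 1.21).
#' @param cluster_covariate_prob Probability a community has the covariate
#'   (default 0.82, a predominantly rural frame).
#' @param prevalence Target marginal outcome prevalence.
#' @param keep_prob Retain per-row probabilities (see
#'   [simulate_clustered()]).
#' @return A tibble in the same schema as [simulate_clustered()].
#' @export
simulate_application <- function(seed = NULL, n_clusters = 850,
                                 mean_size = 5.5, size_range = c(1L, 15L),
                                 sigma2_u = 0.455, alpha = log(1.21),
                                 cluster_covariate_prob = 0.82,
                                 prevalence = 0.63, keep_prob = FALSE) {
  check_sigma2(sigma2_u)
  beta0 <- solve_intercept_for_prevalence(prevalence, sigma2_u, alpha,
                                          cluster_covariate_prob)
  sizes_support <- size_range[1]:size_range[2]
  size_prob <- stats::dpois(sizes_support, mean_size)
  sim <- function() {
    sizes <- sample(sizes_support, n_clusters, replace = TRUE,
                    prob = size_prob)
    simulate_core(sizes, sigma2_u, beta0, 0, 0, alpha,
                  cluster_covariate_prob, keep_prob)
  }
  if (!is.null(seed)) with_local_seed(seed, sim()) else sim()
}

#' Derive the seed for one simulation replicate
#'
#' Replicate `rep` of condition `condition_index` under `base_seed` gets the
#' seed `base_seed + 100000 * condition_index + rep`, so any replicate is
#' reproducible in isolation and results do not depend on execution order.
#'
#' @param base_seed Integer base seed.
#' @param condition_index Zero-based index of the grid condition.
#' @param rep Replicate number (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(base_seed, condition_index, rep) {
  as.integer(base_seed + 100000 * condition_index + rep)
}
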