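test_that("zero variance collapses the marginal likelihood to plain logistic regression", {
  d <- simulate_clustered(8, 6, 0.5, seed = 21)
  beta <- c(0.4, -1.2, 0.25)
  alpha <- -0.3
  eta <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 + alpha * d$xh
  plain <- sum(stats::dbinom(d$y, 1, stats::plogis(eta), log = TRUE))
  expect_equal(marginal_loglik(d, beta, alpha, sigma_u = 0), plain,
               tolerance = 1e-12)
})

test_that("AGQ matches dense-grid integration on tiny datasets", {
  set.seed(14)
  for (i in 1:5) {
    d <- tiny_dataset(sample(2:4, 1), sample(2:5, 1), seed = 100 + i)
    beta <- round(stats::rnorm(3, 0, 0.5), 2)
    alpha <- round(stats::rnorm(1, 0, 0.3), 2)
    sigma_u <- round(stats::runif(1, 0.3, 1), 2)
    expect_equal(marginal_loglik(d, beta, alpha, sigma_u, n_quad = 15),
                 oracle_marginal_loglik(d, beta, alpha, sigma_u),
                 tolerance = 1e-8)
  }
})

test_that("the quadrature is converged by 15 nodes", {
  d <- simulate_clustered(30, 10, 0.8, seed = 9)
  beta <- c(0.5, -1.5, 0.3)
  ll15 <- marginal_loglik(d, beta, -0.3, sqrt(0.8), n_quad = 15)
  ll25 <- marginal_loglik(d, beta, -0.3, sqrt(0.8), n_quad = 25)
  expect_lt(abs(ll15 - ll25) / abs(ll25), 1e-6)
})

test_that("the Laplace error shrinks as cluster size grows", {
  err <- vapply(c(5, 25, 100), function(N) {
    d <- simulate_clustered(20, N, 0.8, seed = 33)
    beta <- c(0.5, -1.5, 0.3)
    abs(marginal_loglik(d, beta, -0.3, sqrt(0.8), n_quad = 1) -
          marginal_loglik(d, beta, -0.3, sqrt(0.8), n_quad = 25))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("loglik and fit are invariant to row and cluster permutations", {
  d <- simulate_clustered(15, 8, 0.5, seed = 11)
  beta <- c(0.5, -1.5, 0.3)
  ll <- marginal_loglik(d, beta, -0.3, 0.7)
  set.seed(1)
  d_perm <- d[sample(nrow(d)), ]
  expect_equal(marginal_loglik(d_perm, beta, -0.3, 0.7), ll,
               tolerance = 1e-10)
  f1 <- fit_ri_logit(d, n_quad = 7)
  f2 <- fit_ri_logit(d_perm, n_quad = 7)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$sigma2_u, f2$sigma2_u, tolerance = 1e-6)
})

test_that("the optimiser finds the grid-search argmax on a tiny dataset", {
  d <- tiny_dataset(3, 4, seed = 55)
  fit <- fit_ri_logit(d, n_quad = 15)
  est <- c(fit$coefficients, fit$sigma_u)
  best <- oracle_grid_argmax(d, centre = c(0, 0, 0, 0, 0.75))
  ll_fit <- fit$loglik
  ll_grid <- marginal_loglik(d, best[1:3], best[4], best[5])
  # The optimiser must do at least as well as the refined exhaustive search
  # and land on the same optimum.
  expect_gte(ll_fit, ll_grid - 1e-4)
  expect_equal(est, best, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("data simulated without clustering is fit at or near the boundary", {
  d <- simulate_clustered(40, 25, 0, seed = 77)
  fit <- fit_ri_logit(d, n_quad = 7)
  expect_lt(fit$sigma2_u, 0.05)
  glm_fit <- stats::glm(y ~ x1 + x2 + xh, data = d, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(glm_fit)),
               tolerance = 0.05)
  if (fit$boundary) {
    expect_identical(fit$sigma2_u, 0)
    expect_true(is.na(fit$std_errors["sigma_u"]))
    expect_equal(unname(fit$coefficients), unname(stats::coef(glm_fit)),
                 tolerance = 1e-6)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- simulate_clustered(50, 20, 0.5, seed = 3)
  fit <- fit_ri_logit(d, n_quad = 7)
  ref <- lme4::glmer(y ~ x1 + x2 + xh + (1 | cluster_id), data = d,
                     family = stats::binomial(), nAGQ = 7)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$sigma2_u, unname(unlist(lme4::VarCorr(ref))),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  d <- simulate_clustered(10, 5, 0.5, seed = 1)
  d_one <- dplyr::mutate(d, y = 1)
  expect_error(fit_ri_logit(d_one), "constant")
  d_single <- dplyr::filter(d, cluster_id == 1)
  expect_error(fit_ri_logit(d_single), "2 clusters")
  expect_error(marginal_loglik(d, c(0, 0), 0, 1), "length 3")
  expect_error(marginal_loglik(d, c(0, 0, 0), 0, -1), ">= 0")
  d_bad <- d
  d_bad$xh[1] <- 1 - d_bad$xh[1]
  expect_error(fit_ri_logit(d_bad), "constant within")
})

test_that("fit_heterogeneity composes the fit with a consistent report", {
  d <- simulate_clustered(40, 15, 0.5, seed = 13)
  res <- fit_heterogeneity(d, n_quad = 7)
  expect_equal(res$report$icc, icc(res$fit$sigma2_u))
  expect_equal(res$report$mor, mor(res$fit$sigma2_u))
  expect_equal(res$report$soi, soi(res$fit$alpha, res$fit$sigma2_u))
  # duality holds for any fitted report
  contains1 <- res$report$ior_lower <= 1 && res$report$ior_upper >= 1
  inside <- res$report$soi > 0.1 && res$report$soi < 0.9
  expect_equal(contains1, inside)
})

test_that("tidy and glance return well-formed summaries", {
  d <- simulate_clustered(30, 10, 0.5, seed = 19)
  fit <- fit_ri_logit(d, n_quad = 5)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x1", "x2", "xh", "sigma_u"))
  expect_true(all(is.finite(td$estimate)))
  expect_true(all(is.finite(td$std.error[1:4])))
  gl <- glance(fit)
  expect_equal(gl$nobs, 300)
  expect_equal(gl$n_clusters, 30)
  expect_true(gl$converged)
})
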