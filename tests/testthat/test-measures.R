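test_that("reference values of the four measures are reproduced", {
  # Analytic values at the study's fixed effects (alpha = -0.3).
  expect_equal(icc(0.5), 0.1319, tolerance = 1e-3)
  expect_equal(icc(1.0), 0.2331, tolerance = 1e-3)
  expect_equal(mor(0.5), 1.963, tolerance = 1e-3)
  expect_equal(mor(1.5), 3.216, tolerance = 1e-3)
  expect_equal(soi(-0.3, 0.5), 0.3821, tolerance = 1e-3)
  expect_equal(soi(-0.3, 1.5), 0.4312, tolerance = 1e-3)
  iv <- ior(-0.3, 0.5)
  expect_equal(iv$ior_lower, 0.2057, tolerance = 1e-3)
  expect_equal(iv$ior_upper, 2.669, tolerance = 1e-3)
  iv <- ior(-0.3, 1.0)
  expect_equal(iv$ior_lower, 0.1209, tolerance = 1e-3)
  expect_equal(iv$ior_upper, 4.538, tolerance = 1e-3)
  # The 0.95-constant shorthand reproduces applied-paper style numbers.
  expect_equal(round(mor(0.455, "0.95"), 3), 1.898)
})

test_that("degenerate zero-variance inputs follow the documented conventions", {
  expect_equal(icc(0), 0)
  expect_equal(mor(0), 1)
  expect_equal(mor(0, "0.95"), 1)
  iv <- ior(-0.3, 0)
  expect_equal(iv$ior_lower, exp(-0.3))
  expect_equal(iv$ior_upper, exp(-0.3))
  expect_equal(soi(-0.3, 0), 0)
  expect_equal(soi(0.3, 0), 1)
  expect_equal(soi(0, 0), 0.5)
  expect_equal(soi(0, 2.5), 0.5)
  expect_equal(icc(pi^2 / 3), 0.5)  # equal variance components
})

test_that("domain errors are raised for invalid inputs", {
  expect_error(icc(-0.1), "non-negative")
  expect_error(mor(-1), "non-negative")
  expect_error(soi(0.2, -0.5), "non-negative")
  expect_error(ior(0.2, 0.5, interval_mass = 0), "between 0 and 1")
  expect_error(ior(0.2, 0.5, interval_mass = 1.2), "between 0 and 1")
  expect_error(soi(NA, 0.5), "finite")
})

test_that("measures agree with a root-finding oracle to 10 significant digits", {
  set.seed(42)
  for (i in 1:25) {
    alpha <- stats::runif(1, -2, 2)
    s2 <- stats::runif(1, 0.01, 3)
    mass <- stats::runif(1, 0.5, 0.95)
    o <- oracle_measures(alpha, s2, mass)
    expect_equal(icc(s2), o$icc, tolerance = 1e-10)
    expect_equal(mor(s2), o$mor, tolerance = 1e-10)
    expect_equal(soi(alpha, s2), o$soi, tolerance = 1e-10)
    iv <- ior(alpha, s2, mass)
    expect_equal(iv$ior_lower, o$ior_lower, tolerance = 1e-10)
    expect_equal(iv$ior_upper, o$ior_upper, tolerance = 1e-10)
  }
})

test_that("IOR is log-symmetric about alpha and SOI obeys the reflection identity", {
  set.seed(7)
  for (i in 1:50) {
    alpha <- stats::runif(1, -3, 3)
    s2 <- stats::runif(1, 0, 4)
    mass <- stats::runif(1, 0.05, 0.95)
    iv <- ior(alpha, s2, mass)
    expect_lte(iv$ior_lower, iv$ior_upper)
    expect_equal(log(iv$ior_lower) + log(iv$ior_upper), 2 * alpha,
                 tolerance = 1e-12)
    expect_equal(soi(alpha, s2) + soi(-alpha, s2), 1, tolerance = 1e-12)
  }
})

test_that("the IOR interval contains 1 exactly when the SOI is inside the mass tails", {
  set.seed(11)
  for (i in 1:200) {
    alpha <- stats::runif(1, -3, 3)
    s2 <- stats::runif(1, 0.01, 4)
    mass <- stats::runif(1, 0.1, 0.95)
    iv <- ior(alpha, s2, mass)
    contains1 <- iv$ior_lower <= 1 && iv$ior_upper >= 1
    s <- soi(alpha, s2)
    inside <- s > (1 - mass) / 2 && s < 1 - (1 - mass) / 2
    # Boundary equalities are measure-zero under runif; strict duality holds.
    expect_equal(contains1, inside)
  }
})

test_that("ICC and MOR are strictly increasing in the variance, MOR >= 1", {
  s2 <- seq(0, 5, length.out = 400)
  expect_true(all(diff(icc(s2)) > 0))
  expect_true(all(diff(mor(s2)) > 0))
  expect_true(all(mor(s2) >= 1))
  expect_true(all(icc(s2) >= 0 & icc(s2) < 1))
  # MOR is invariant to alpha by construction (no alpha argument) while the
  # IOR width grows with the variance.
  w <- ior(-0.3, s2)$ior_upper / ior(-0.3, s2)$ior_lower
  expect_true(all(diff(w[-1]) > 0))
})

test_that("the true-values table echoes inputs and is monotone in the variance", {
  tab <- true_values_table()
  expect_equal(nrow(tab), 4)
  expect_equal(tab$sigma2_u, c(0.2, 0.5, 1.0, 1.5))
  expect_true(all(tab$beta0 == 0.5 & tab$beta1 == -1.5 &
                    tab$beta2 == 0.3 & tab$alpha == -0.3))
  expect_true(all(diff(tab$icc) > 0))
  expect_true(all(diff(tab$mor) > 0))
  expect_true(all(diff(tab$ior_upper / tab$ior_lower) > 0))
  # Degenerate grid: no heterogeneity collapses MOR and the interval.
  tab0 <- true_values_table(sigma2_u = 0)
  expect_equal(tab0$mor, 1)
  expect_equal(tab0$ior_lower, exp(-0.3))
  expect_equal(tab0$ior_upper, exp(-0.3))
})

test_that("heterogeneity_report is internally consistent with the components", {
  rep_ <- heterogeneity_report(0.2, 0.3)
  expect_equal(rep_$icc, icc(0.3))
  expect_equal(rep_$mor, mor(0.3))
  expect_equal(rep_$soi, soi(0.2, 0.3))
  o <- oracle_measures(0.2, 0.3)
  expect_equal(rep_$ior_lower, o$ior_lower, tolerance = 1e-10)
  expect_equal(rep_$ior_upper, o$ior_upper, tolerance = 1e-10)
  rep0 <- heterogeneity_report(0, 0)
  expect_equal(rep0$icc, 0)
  expect_equal(rep0$mor, 1)
  expect_equal(rep0$soi, 0.5)
  expect_equal(c(rep0$ior_lower, rep0$ior_upper), c(1, 1))
})
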