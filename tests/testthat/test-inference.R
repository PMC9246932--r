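test_that("permutation tests behave at the boundaries", {
  set.seed(40)
  x <- rnorm(20)
  # identical groups: p near 1
  res <- permutation_test(x, x, n_perm = 500, correction = "none", seed = 1)
  expect_gt(res$p, 0.5)
  # single variable: tmax equals the uncorrected p (same permutations)
  r1 <- permutation_test(matrix(x, ncol = 1), tail = "right", n_perm = 1000,
                         correction = "tmax", seed = 2)
  r2 <- permutation_test(matrix(x, ncol = 1), tail = "right", n_perm = 1000,
                         correction = "none", seed = 2)
  expect_equal(r1$p, r2$p_uncorrected)
  # add-one estimator: p can never be zero and is bounded below
  big <- permutation_test(matrix(rnorm(30, 5), ncol = 1), n_perm = 200, seed = 3)
  expect_gte(big$p, 1 / 201)
  expect_error(permutation_test(x, n_perm = 0), "n_perm")
})

test_that("one-sample permutation t matches the analytic t statistic", {
  set.seed(41)
  x <- matrix(rnorm(60), 20, 3)
  res <- permutation_test(x, n_perm = 10, seed = 1)
  expect_equal(res$statistic,
               apply(x, 2, function(c) t.test(c)$statistic),
               ignore_attr = TRUE, tolerance = 1e-10)
  y <- matrix(rnorm(45), 15, 3)
  res2 <- permutation_test(x, y, n_perm = 10, seed = 1)
  expect_equal(res2$statistic,
               vapply(1:3, function(j) t.test(x[, j], y[, j],
                                              var.equal = TRUE)$statistic,
                      numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("permutation p-values are valid under the null", {
  set.seed(42)
  ps <- vapply(1:200, function(i) {
    permutation_test(matrix(rnorm(12), ncol = 1), n_perm = 99)$p
  }, numeric(1))
  # stochastically >= uniform: empirical rejection at 0.05 not inflated
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("BCa intervals degrade gracefully and track skew", {
  const <- bootstrap_ci(rep(3, 10), mean, n_boot = 200, seed = 1)
  expect_equal(const$ci, c(3, 3))

  set.seed(43)
  skewed <- rexp(60)
  b <- bootstrap_ci(skewed, mean, n_boot = 4000, seed = 2)
  expect_lt(b$ci[1], mean(skewed))
  expect_gt(b$ci[2], mean(skewed))
  # vs plain percentile: BCa shifts toward the long right tail
  set.seed(2)
  bs <- replicate(4000, mean(sample(skewed, 60, replace = TRUE)))
  perc <- quantile(bs, c(0.025, 0.975))
  expect_gte(b$ci[2], perc[[2]] - 1e-9)
  expect_error(bootstrap_ci(1:2, mean), "at least 3")
})

test_that("Hedge's g is bias-corrected, antisymmetric and calibrated", {
  x <- rnorm(30); y <- rnorm(30)
  g1 <- hedges_g(x, y, n_boot = 0)
  g2 <- hedges_g(y, x, n_boot = 0)
  expect_equal(g1$g, -g2$g)
  expect_equal(hedges_g(x, x, n_boot = 0)$g, 0)
  expect_true(hedges_g(rep(1, 5), rep(1, 5), n_boot = 0)$undefined)

  set.seed(44)
  gs <- vapply(1:200, function(i) {
    hedges_g(rnorm(150, 0.5), rnorm(150, 0), n_boot = 0)$g
  }, numeric(1))
  expect_lt(abs(median(gs) - 0.5), 0.05)

  ci <- hedges_g(rnorm(40, 1), rnorm(40), n_boot = 500, seed = 3)
  expect_lt(ci$ci[1], ci$g)
  expect_gt(ci$ci[2], ci$g)
})

test_that("JZS Bayes factors favour the null at t = 0 and decrease in |t|", {
  bf0 <- bayes_factor_t(0, 30, 30)
  expect_gt(bf0, 1)
  bfs <- vapply(c(0, 1, 2, 3, 4), function(t) bayes_factor_t(t, 30, 30),
                numeric(1))
  expect_true(all(diff(bfs) < 0))
  # scale-1 Cauchy prior: a huge t yields overwhelming evidence against null
  expect_lt(bayes_factor_t(6, 40, 40), 0.01)
})

test_that("the RIN transform is monotone, centred and rank-preserving", {
  set.seed(45)
  x <- rexp(101)
  r <- rin_transform(x)
  expect_equal(order(x), order(r))
  expect_lt(abs(mean(r)), 0.02)
  y <- x^2 + rexp(101)
  expect_equal(cor(x, y, method = "spearman"),
               cor(rin_transform(x), rin_transform(y), method = "spearman"))
  expect_error(rin_transform(rep(1, 5)), "tied")
})

test_that("partial correlations remove covariate-shared variance", {
  set.seed(46)
  covar <- rnorm(80)
  y <- covar
  x <- rnorm(80)
  expect_lt(abs(partial_correlation(x, y + 1e-8 * rnorm(80), covar,
                                    n_perm = 0)$r), 0.05)
  # shared variance independent of the covariate survives
  shared <- rnorm(80)
  pc <- partial_correlation(shared + rnorm(80, 0, 0.5) + covar,
                            shared + rnorm(80, 0, 0.5) - covar,
                            covar, n_perm = 500, seed = 1)
  expect_gt(pc$r, 0.3)
  expect_lt(pc$p_perm, 0.05)
  # constant covariate: reduces to the ordinary correlation
  pc0 <- partial_correlation(x, shared, rep(1, 80), n_perm = 0)
  expect_equal(pc0$r, cor(x, shared), tolerance = 1e-10)
})

test_that("mediation paths obey OLS algebra and classify path structures", {
  set.seed(47)
  n <- 200
  age <- rnorm(n)
  mse <- 0.5 * age + rnorm(n, 0, 0.8)
  gain <- 0.4 * age + 0.3 * mse + rnorm(n, 0, 0.8)
  m <- mediation_analysis(age, mse, gain, n_boot = 1000, seed = 1)
  expect_lt(abs(m$ab$estimate + m$c_prime$estimate - m$c$estimate), 1e-10)
  expect_equal(m$mediation, "partial")
  expect_lt(m$ab$p, 0.05)

  # mediator independent of age: no mediation, full direct path
  m0 <- mediation_analysis(age, rnorm(n), 0.5 * age + rnorm(n, 0, 0.5),
                           n_boot = 1000, seed = 2)
  expect_equal(m0$mediation, "none")
  expect_lt(m0$c_prime$p, 0.05)
  expect_error(mediation_analysis(1:5, 1:5, 1:5), "at least 10")
})

test_that("full mediation is classified reliably when the truth is full", {
  set.seed(48)
  hits <- vapply(1:200, function(i) {
    n <- 200
    age <- rnorm(n)
    mse <- 0.6 * age + rnorm(n, 0, 0.7)
    gain <- 0.6 * mse + rnorm(n, 0, 0.7)  # age acts only through mse
    mediation_analysis(age, mse, gain, n_boot = 400)$mediation == "full"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
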