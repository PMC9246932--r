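grid_cdf <- function(p, times = seq(200, 600, length.out = length(p))) {
  quantile_cdf(p, times)
}

test_that("Raab race follows probability summation exactly", {
  f <- grid_cdf(seq(0.05, 1, length.out = 20))
  expect_equal(raab_race(f, f)$probs, 2 * f$probs - f$probs^2)

  fa <- grid_cdf(c(0.2, 0.5)); fv <- grid_cdf(c(0.1, 0.4))
  expect_equal(raab_race(fa, fv)$probs, c(0.28, 0.70))
  expect_error(raab_race(fa, grid_cdf(c(0.1, 0.4), times = c(1, 2))),
               "share")
})

test_that("Raab race matches a min-latency simulation oracle", {
  set.seed(10)
  a <- rnorm(400, 420, 70)
  v <- rnorm(400, 460, 80)
  lim <- c(250, 650)
  fa <- empirical_cdf(a, lim)
  fv <- empirical_cdf(v, lim)
  race <- raab_race(fa, fv)
  # oracle: 1e6 independent paired draws, response = faster channel
  n <- 1e6
  mins <- pmin(sample(a, n, replace = TRUE), sample(v, n, replace = TRUE))
  mc <- vapply(race$eval_times_ms, function(t) mean(mins <= t), numeric(1))
  expect_lt(max(abs(race$probs - mc)), 0.005)
})

test_that("Grice and Miller bounds bracket the race model", {
  f <- grid_cdf(seq(0.05, 0.95, length.out = 20))
  b <- race_bounds(f, f)
  expect_equal(b$grice$probs, f$probs)
  expect_equal(b$miller$probs, pmin(2 * f$probs, 1))
  expect_equal(race_bounds(grid_cdf(0.7, 300), grid_cdf(0.6, 300))$miller$probs, 1)

  set.seed(11)
  for (i in 1:20) {
    fa <- grid_cdf(sort(runif(20)))
    fv <- grid_cdf(sort(runif(20)))
    b <- race_bounds(fa, fv)
    r <- raab_race(fa, fv)
    expect_true(all(b$grice$probs <= r$probs + 1e-12))
    expect_true(all(r$probs <= b$miller$probs + 1e-12))
  }
})

test_that("benefit AUCs use the rectangle rule on the quantile interval", {
  race <- grid_cdf(seq(0.1, 0.9, length.out = 20))
  grice <- grid_cdf(race$probs - 0.1)
  fav <- grice
  ben <- race_benefits(fav, race, grice)
  expect_equal(ben$benefit_emp, 0)
  expect_equal(ben$benefit_pred, 0.1)

  # discretisation property: mean rule vs trapezoid differs < 1/40 of range
  set.seed(12)
  for (i in 1:10) {
    d <- sort(runif(20)) - sort(runif(20))
    trap <- sum((d[-1] + d[-20]) / 2) / 19
    expect_lt(abs(mean(d) - trap), (max(d) - min(d)) / 40 + 1e-12)
  }
})

test_that("gain equals the benefit difference and splits into signed areas", {
  set.seed(13)
  for (i in 1:10) {
    fa <- grid_cdf(sort(runif(20)))
    fv <- grid_cdf(sort(runif(20)))
    fav <- grid_cdf(sort(runif(20)))
    race <- raab_race(fa, fv)
    grice <- race_bounds(fa, fv)$grice
    ben <- race_benefits(fav, race, grice)
    g <- multisensory_gain(fav, race)
    expect_lt(abs(g$gain - (ben$benefit_emp - ben$benefit_pred)), 1e-12)
    expect_lt(abs(g$gain - (g$auc_pos + g$auc_neg)), 1e-12)
  }
  f <- grid_cdf(seq(0.1, 0.9, length.out = 20))
  expect_equal(multisensory_gain(f, f)$gain, 0)
})

test_that("the conditioned race collapses and falls back as specified", {
  pa <- sort(runif(20)); pv <- sort(runif(20)); pav <- sort(runif(20))
  cs <- flat_cdfset(pa, pv, pav)
  expect_equal(conditioned_race(cs)$probs,
               raab_race(cs$cdf$A, cs$cdf$V)$probs)

  # one degenerate stratum: that term uses the unconditioned CDF
  cs2 <- cs
  cs2$by_prev$A$AV <- NULL
  expect_warning(r2 <- conditioned_race(cs2), "degenerate")
  expect_equal(r2$probs, raab_race(cs$cdf$A, cs$cdf$V)$probs)
})

test_that("slowed-switch data make the conditioned race less conservative", {
  # with a switch cost, unisensory switch trials are slow; conditioning on
  # preceding modality lets the race prediction use the faster repeat
  # distributions where appropriate, raising it at some quantiles
  diffs <- vapply(1:24, function(i) {
    tr <- make_subject(900, seed = 700 + i, switch_cost = 0.45)
    cs <- condition_subsets(tr)
    mean(conditioned_race(cs)$probs -
           raab_race(cs$cdf$A, cs$cdf$V)$probs)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("race violation tests flag injected facilitation and only that", {
  set.seed(14)
  null_d <- matrix(rnorm(50 * 20, 0, 0.05), 50, 20)
  res0 <- race_violation_test(matrix(0, 10, 20), n_perm = 500, seed = 1)
  expect_true(all(!res0$significant))

  inj <- null_d
  inj[, 1:3] <- inj[, 1:3] + 0.08  # large facilitation at quantiles 1-3
  res <- race_violation_test(inj, n_perm = 2000, seed = 2)
  expect_true(all(res$significant[1:3]))
  expect_true(all(!res$significant[4:20]))
  expect_error(race_violation_test(matrix(0, 1, 20)), "2 subjects")
})
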