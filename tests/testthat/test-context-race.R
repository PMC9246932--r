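test_that("LATER fits recover rate parameters and flag degenerates", {
  set.seed(30)
  x <- rnorm(5000, 5, 1)
  x <- x[x > 0]
  f <- fit_later(1000 / x)
  expect_gt(f$mu, 4.95); expect_lt(f$mu, 5.05)
  expect_gt(f$sigma, 0.95); expect_lt(f$sigma, 1.05)

  expect_true(fit_later(rep(400, 30))$degenerate)
  expect_error(fit_later(c(rep(400, 25), -5)), "positive")
  expect_error(fit_later(rep(400, 5)), "at least")

  # location equivariance on the rate scale
  f2 <- fit_later(1000 / (x + 2))
  expect_equal(f2$mu, f$mu + 2, tolerance = 1e-10)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-10)
})

test_that("the predicted AV distribution reduces correctly in special cases", {
  ts <- seq(220, 700, length.out = 20)
  fit0 <- list(mu_a = 3, sigma_a = 0.6, mu_v = 2.7, sigma_v = 0.5,
               rho = 0, eta = 0)
  pred <- predict_av_distribution(fit0, ts)
  # independence: race of the two LATER channel CDFs
  fa <- 1 - pnorm((1000 / ts - 3) / 0.6)
  fv <- 1 - pnorm((1000 / ts - 2.7) / 0.5)
  expect_lt(max(abs(pred$probs - (fa + fv - fa * fv))), 0.01)

  # perfect coupling with equal channels: the unisensory distribution
  fit1 <- list(mu_a = 3, sigma_a = 0.6, mu_v = 3, sigma_v = 0.6,
               rho = 1, eta = 0)
  pred1 <- predict_av_distribution(fit1, ts)
  expect_lt(max(abs(pred1$probs - fa)), 1e-4)

  # monotone, bounded for admissible parameters
  for (rho in c(-0.8, 0.4)) {
    p <- predict_av_distribution(utils::modifyList(fit0, list(rho = rho, eta = 0.3)), ts)
    expect_true(all(diff(p$probs) >= -1e-12))
    expect_true(all(p$probs >= 0 & p$probs <= 1))
  }
  expect_error(predict_av_distribution(utils::modifyList(fit0, list(eta = -1)), ts),
               "invalid")
})

test_that("the predicted AV CDF matches a bivariate Monte-Carlo oracle", {
  fit <- list(mu_a = 3, sigma_a = 0.6, mu_v = 2.8, sigma_v = 0.55,
              rho = -0.5, eta = 0.2)
  ts <- seq(230, 650, length.out = 20)
  pred <- predict_av_distribution(fit, ts)
  set.seed(31)
  n <- 1e6
  z1 <- rnorm(n); z2 <- rnorm(n)
  xa <- 3 + 0.6 * 1.2 * z1
  xv <- 2.8 + 0.55 * 1.2 * (-0.5 * z1 + sqrt(0.75) * z2)
  mx <- pmax(xa, xv)
  mc <- vapply(ts, function(t) mean(mx >= 1000 / t), numeric(1))
  expect_lt(max(abs(pred$probs - mc)), 0.005)
})

test_that("rho and eta are recovered from the generator's own data", {
  res <- vapply(1:20, function(r) {
    sq <- sample_trial_sequence(1300, seed = 800 + r)
    tr <- generate_subject_trials(base_params(rho = -0.5, eta = 0.2), sq,
                                  seed = 900 + r)
    f <- fit_context_race(tr$rt_ms[tr$condition == "A"],
                          tr$rt_ms[tr$condition == "V"],
                          tr$rt_ms[tr$condition == "AV"][1:400])
    c(f$rho, f$eta)
  }, numeric(2))
  expect_lt(median(abs(res[1, ] + 0.5)), 0.15)
  expect_lt(median(abs(res[2, ] - 0.2)), 0.1)

  # null recovery: independent race data
  res0 <- vapply(1:10, function(r) {
    sq <- sample_trial_sequence(1300, seed = 820 + r)
    tr <- generate_subject_trials(base_params(), sq, seed = 920 + r)
    f <- fit_context_race(tr$rt_ms[tr$condition == "A"],
                          tr$rt_ms[tr$condition == "V"],
                          tr$rt_ms[tr$condition == "AV"])
    c(f$rho, f$eta)
  }, numeric(2))
  expect_lt(abs(median(res0[1, ])), 0.15)
  expect_lt(abs(median(res0[2, ])), 0.1)

  expect_error(fit_context_race(rnorm(100, 400, 40), rnorm(100, 420, 40),
                                rnorm(5, 350, 30)), "at least")
})

test_that("the recovered optimum beats the independent-race likelihood", {
  sq <- sample_trial_sequence(1300, seed = 840)
  tr <- generate_subject_trials(base_params(rho = -0.6, eta = 0.15), sq,
                                seed = 940)
  f <- fit_context_race(tr$rt_ms[tr$condition == "A"],
                        tr$rt_ms[tr$condition == "V"],
                        tr$rt_ms[tr$condition == "AV"])
  rate_av <- 1000 / tr$rt_ms[tr$condition == "AV" & !is.na(tr$rt_ms)]
  nll0 <- multirace:::context_race_nll(c(0, 0), rate_av, f$mu_a, f$sigma_a,
                                       f$mu_v, f$sigma_v)
  expect_lte(f$objective, nll0)
  expect_true(f$converged)
})

test_that("switch trials crowd into the slow quantiles under a switch cost", {
  tr <- make_subject(2500, seed = 180, switch_cost = 0.5)
  prof <- switch_repeat_frequency_profile(tr)
  frac <- prof$n_switch / pmax(prof$n_switch + prof$n_repeat, 1)
  half <- nrow(prof) %/% 2
  expect_gt(mean(frac[(half + 1):nrow(prof)], na.rm = TRUE),
            mean(frac[1:half], na.rm = TRUE))

  # no switch cost: roughly flat profile
  tr0 <- make_subject(2500, seed = 181)
  prof0 <- switch_repeat_frequency_profile(tr0)
  frac0 <- prof0$n_switch / pmax(prof0$n_switch + prof0$n_repeat, 1)
  expect_lt(abs(mean(frac0[(half + 1):nrow(prof0)], na.rm = TRUE) -
                  mean(frac0[1:half], na.rm = TRUE)), 0.06)

  one <- manual_trials(c("A", "A"), c(400, 400), trial_idx = 4:5)
  p1 <- switch_repeat_frequency_profile(one)
  expect_equal(sum(p1$n_switch + p1$n_repeat), 1)
})
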