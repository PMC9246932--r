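test_that("the CDF-based switch effect is a signed, bounded, antisymmetric area", {
  f1 <- quantile_cdf(seq(0.1, 0.9, length.out = 20), 1:20)
  f2 <- quantile_cdf(f1$probs - 0.1, 1:20)
  expect_equal(mse_auc(f1, f1), 0)
  expect_equal(mse_auc(f1, f2), 0.1)
  set.seed(20)
  for (i in 1:10) {
    a <- quantile_cdf(sort(runif(20)), 1:20)
    b <- quantile_cdf(sort(runif(20)), 1:20)
    expect_equal(mse_auc(a, b), -mse_auc(b, a))
    expect_lte(abs(mse_auc(a, b)), max(abs(a$probs - b$probs)))
  }
})

test_that("per-condition switch effects include separated and pooled AV", {
  tr <- make_subject(1200, seed = 130, switch_cost = 0.4)
  m <- mse_by_condition(condition_subsets(tr))
  expect_setequal(m$condition, c("V->A", "A->V", "V/A->AV", "A->AV", "V->AV"))
  # with a per-channel switch cost, unisensory switch effects are positive
  expect_gt(m$mse_auc[m$condition == "V->A"], 0)
  expect_gt(m$mse_auc[m$condition == "A->V"], 0)
})

test_that("group-level normalisation flags a zero reference", {
  tab <- data.frame(condition = c("V/A->AV", "A->AV", "V->AV"),
                    mse_auc = c(0.05, 0.04, 0.06))
  nm <- normalise_av_mse(tab)
  expect_equal(nm$a_to_av, 0.8)
  expect_equal(nm$v_to_av, 1.2)
  tab0 <- tab; tab0$mse_auc[1] <- 0
  expect_false(normalise_av_mse(tab0)$ok)
  # equal separated effects normalise to 1
  tab1 <- data.frame(condition = c("V/A->AV", "A->AV", "V->AV"),
                     mse_auc = c(0.05, 0.05, 0.05))
  expect_equal(normalise_av_mse(tab1)$a_to_av, 1)
})

test_that("A-driven AV responses produce a larger V->AV switch effect", {
  # responses on AV trials follow the auditory channel, so a preceding V
  # (which penalises the A channel) slows AV responses more than a
  # preceding A does
  vals <- t(vapply(1:12, function(i) {
    tr <- make_subject(1500, seed = 140 + i, switch_cost = 0.45,
                       competition_mode = "model1A", p_competition = 1)
    m <- mse_by_condition(condition_subsets(tr))
    c(a = m$mse_auc[m$condition == "A->AV"],
      v = m$mse_auc[m$condition == "V->AV"])
  }, numeric(2)))
  expect_gt(mean(vals[, "v"] - vals[, "a"]), 0)
  expect_gt(sum(vals[, "v"] > vals[, "a"]), 6)
})

test_that("mean-RT switch effects respond to ISI restriction and shifts", {
  tr <- manual_trials(rep(c("A", "A", "V", "A"), 50),
                      rep(c(400, 400, 410, 430), 50),
                      block = rep(1:2, each = 100),
                      trial_idx = rep(4:103, 2))
  # A->A repeats at 400 (after V->A switches at 430)
  an <- annotate_sequence(clean_rts(tr))
  sw <- an$rt_ms[an$rt_valid & an$condition == "A" & an$transition %in% "switch"]
  rp <- an$rt_ms[an$rt_valid & an$condition == "A" & an$transition %in% "repeat"]
  expect_equal(mse_mean_rt(tr, conditions = "A"), mean(sw) - mean(rp))

  same <- manual_trials(rep(c("A", "A", "V", "V"), 50), rep(500, 200),
                        trial_idx = rep(4:103, 2), block = rep(1:2, each = 100))
  expect_equal(mse_mean_rt(same), 0)

  # a switch cost that decays with ISI shrinks the long-ISI estimate
  long_short <- vapply(1:10, function(i) {
    tr2 <- make_subject(2500, seed = 150 + i, switch_cost = 0.5,
                        switch_cost_isi_tau = 800)
    c(all = mse_mean_rt(tr2),
      long = mse_mean_rt(tr2, isi_window = c(2500, 3000)))
  }, numeric(2))
  expect_gt(mean(long_short["all", ] - long_short["long", ]), 0)
  expect_error(mse_mean_rt(same[1:2, ]), "empty")
})

test_that("switch and repeat CDFs mix back to the classifiable-condition CDF", {
  tr <- make_subject(900, seed = 160, switch_cost = 0.3)
  cs <- condition_subsets(tr)
  cl <- cs$trials
  for (cc in c("A", "V")) {
    sub <- cl[cl$condition == cc & !is.na(cl$transition), ]
    n_s <- sum(sub$transition == "switch")
    n_r <- sum(sub$transition == "repeat")
    mixed <- (n_s * cs$switch[[cc]]$probs + n_r * cs$repeat_[[cc]]$probs) /
      (n_s + n_r)
    full <- empirical_cdf(sub$rt_ms, cs$limits)$probs
    expect_equal(mixed, full, tolerance = 1e-12)
  }
})

test_that("gain is larger on switch trials when the cost hits unisensory channels", {
  res <- vapply(1:16, function(i) {
    tr <- make_subject(1500, seed = 170 + i, switch_cost = 0.45)
    rbs <- race_by_switch(tr)
    if (is.null(rbs)) return(NA_real_)
    rbs$gain_switch - rbs$gain_repeat
  }, numeric(1))
  res <- res[!is.na(res)]
  expect_gt(sum(res > 0), length(res) * 0.6)

  # without a switch cost the paired difference is centred on zero
  null_d <- vapply(1:16, function(i) {
    rbs <- race_by_switch(make_subject(1500, seed = 190 + i))
    if (is.null(rbs)) return(NA_real_)
    rbs$gain_switch - rbs$gain_repeat
  }, numeric(1))
  null_d <- null_d[!is.na(null_d)]
  expect_gt(t.test(null_d)$p.value, 0.01)
})
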