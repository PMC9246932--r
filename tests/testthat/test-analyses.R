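test_that("similarity matrices are exact for self-comparison", {
  set.seed(50)
  d <- matrix(rnorm(40), 2, 20)
  sm <- similarity_matrices(rbind(d, d), ages = c(7, 12, 7, 12),
                            groups = c("g1", "g1", "g2", "g2"))
  # each row bin's duplicate sits in the matching column bin
  expect_equal(sm$rmse[1, 1], 0)
  expect_equal(sm$corr[1, 1], 1)
})

test_that("a developmental lag shifts the extremal trace below the diagonal", {
  set.seed(51)
  # difference functions evolve with age; group 2 lags by 5 years (2 bins)
  shape <- function(a) 0.01 * (a - 6) * sin(seq(0, pi, length.out = 20)) +
    0.002 * (a - 6)
  mk <- function(ages, lag) t(vapply(ages, function(a) {
    shape(a - lag) + rnorm(20, 0, 0.004)
  }, numeric(20)))
  ages1 <- runif(120, 6, 21); ages2 <- runif(120, 6, 21)
  dmat <- rbind(mk(ages1, 0), mk(ages2, 5))
  grp <- rep(c("NT", "ASD"), each = 120)
  sm <- similarity_matrices(dmat, c(ages1, ages2), groups = grp,
                            row_group = "ASD", col_group = "NT")
  lag_bins <- sm$trace_rmse - seq_along(sm$trace_rmse)
  expect_lt(mean(lag_bins, na.rm = TRUE), -1)  # best match ~2 bins younger
  expect_gt(mean(lag_bins, na.rm = TRUE), -3)

  # the lag signature: row/column bins two steps apart match better than
  # same-age bins
  shifted_gain <- function(s) {
    rows <- 3:6
    mean(s$rmse[cbind(rows, rows)]) - mean(s$rmse[cbind(rows, rows - 2)])
  }
  expect_gt(shifted_gain(sm), 0)
  # null control: permuted ages carry no such alignment structure
  sm0 <- similarity_matrices(dmat, sample(c(ages1, ages2)), groups = grp,
                             row_group = "ASD", col_group = "NT")
  expect_lt(abs(shifted_gain(sm0)), 0.5 * shifted_gain(sm))
})

test_that("participant matching is exact, deterministic and distance-greedy", {
  cases <- data.frame(subject_id = c("C1", "C2"), sex = c("F", "M"),
                      age_years = c(8, 20), piq = c(100, 110))
  pool <- data.frame(subject_id = c("P1", "P2", "P3", "P4"),
                     sex = c("F", "M", "F", "M"),
                     age_years = c(8, 20, 14, 30), piq = c(100, 110, 90, 100))
  m <- match_participants(cases, pool)
  expect_equal(m$control_id, c("P1", "P2"))  # exact duplicates selected
  expect_equal(m$distance, c(0, 0))

  # tie: two equidistant same-sex candidates, lower id wins
  pool2 <- data.frame(subject_id = c("P9", "P2"), sex = "F",
                      age_years = c(9, 7), piq = c(100, 100))
  m2 <- match_participants(cases[1, ], pool2)
  expect_equal(m2$control_id, "P2")

  # no same-sex control left
  m3 <- match_participants(cases, pool[pool$sex == "F", ])
  expect_false(m3$matched[2])

  # matched groups are closer in age than random subsets
  set.seed(52)
  big_pool <- data.frame(subject_id = sprintf("P%03d", 1:100),
                         sex = sample(c("F", "M"), 100, TRUE),
                         age_years = runif(100, 6, 40),
                         piq = rnorm(100, 105, 12))
  cs <- data.frame(subject_id = sprintf("C%02d", 1:20), sex = "F",
                   age_years = runif(20, 6, 40), piq = rnorm(20, 105, 12))
  mm <- match_participants(cs, big_pool)
  matched_diff <- abs(mean(big_pool$age_years[match(mm$control_id, big_pool$subject_id)]) -
                        mean(cs$age_years))
  rand_diff <- mean(replicate(100, {
    abs(mean(sample(big_pool$age_years, 20)) - mean(cs$age_years))
  }))
  expect_lt(matched_diff, rand_diff + 0.5)
})

test_that("moving windows collapse to a whole-sample test and stay null-quiet", {
  set.seed(53)
  ages <- runif(60, 10, 12)
  grp <- rep(c("ASD", "NT"), 30)
  met <- rnorm(60)
  # step larger than the range: single window containing everyone
  mw <- moving_window_compare(met, ages, grp, window = 40, step = 50,
                              centers = 11, n_perm = 500, n_boot = 200,
                              seed = 9)
  expect_equal(nrow(mw), 1)
  expect_equal(mw$n1 + mw$n2, 60)
  whole <- permutation_test(met[grp == "ASD"], met[grp == "NT"],
                            n_perm = 500, correction = "none",
                            seed = stage_seed(9, "win_11"))
  expect_equal(mw$p_perm, whole$p)
  # identical groups: no significant windows, BF favours the null
  expect_true(all(!mw$significant))
  expect_gt(mw$bf01, 1)
})

test_that("windowed group differences are confined to where they exist", {
  set.seed(54)
  n <- 260
  ages <- runif(n, 6, 26)
  grp <- rep(c("ASD", "NT"), n / 2)
  eff <- ifelse(grp == "ASD" & ages < 14, -1.0, 0)
  met <- eff + rnorm(n, 0, 0.8)
  mw <- moving_window_compare(met, ages, grp, window = 7, step = 1,
                              centers = 6:26, n_perm = 1000, n_boot = 200,
                              seed = 10)
  sig_centers <- mw$center[mw$significant]
  expect_gt(length(sig_centers), 0)
  expect_true(all(sig_centers < 16))  # windows centred >= 16 contain no signal
})

test_that("the RT mixed model recovers injected group and age effects", {
  cfg <- cohort_config(n_nt = 10, n_asd = 10, n_blocks = 4,
                       asd_mu_shift = -0.35, asd_shift_max_age = 41,
                       asd_rho_shift = 0, seed = 61)
  coh <- generate_cohort(cfg)
  fit <- fit_rt_lmm(coh$trials, coh$subjects)
  co <- fit$coefficients
  expect_gt(co$estimate[co$term == "group_c"], 0)      # ASD slower
  expect_lt(co$estimate[co$term == "age_years"], 0)    # older faster
  expect_lt(co$p[co$term == "age_years"], 0.05)
  # unisensory conditions slower than the AV reference
  expect_gt(co$estimate[co$term == "conditionA"], 0)
  expect_gt(co$estimate[co$term == "conditionV"], 0)
})

test_that("the benefit ANCOVA separates slope, group and interaction", {
  set.seed(55)
  grp <- factor(rep(c("6-9", "18-40"), each = 40))
  pred <- runif(80, 0, 0.1)
  # slope increases with age group
  slope <- ifelse(grp == "6-9", 0.2, 1.2)
  emp <- slope * pred + rnorm(80, 0, 0.01)
  res <- ancova_benefit_correlation(pred, emp, grp)
  expect_lt(res$p_pred, 0.05)
  expect_lt(res$p_interaction, 0.05)
  expect_gt(res$group_r[["18-40"]], res$group_r[["6-9"]])

  # identical slope: interaction non-significant over replicates is the
  # expectation; a single draw should at least not reject strongly
  emp0 <- 0.5 * pred + rnorm(80, 0, 0.02)
  res0 <- ancova_benefit_correlation(pred, emp0, grp)
  expect_gt(res0$p_interaction, 0.001)

  # one group collapses to a simple regression
  res1 <- ancova_benefit_correlation(pred[grp == "6-9"], emp[grp == "6-9"],
                                     grp[grp == "6-9"])
  expect_true(is.na(res1$f_interaction))
  expect_lt(res1$p_pred, 0.05)
})
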