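## Synthetic cohort generator -------------------------------------------------
##
## Emulates the trial and RT structure of an interleaved audiovisual (AV)
## detection task: three equiprobable stimulus conditions in random order,
## ISIs uniform on 1000-3000 ms, blocks of ~100 trials, per-channel RT
## distributions whose reciprocals are approximately normal (LATER), a
## within-trial channel correlation rho and multisensory noise inflation eta,
## rate-scale switch costs on modality transitions, and optional competition
## modes in which the AV response is triggered by a biased channel.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Configuration for a synthetic bisensory detection cohort
#'
#' Channel processing rates are expressed on the LATER scale (1/s): a trial's
#' RT in ms is `1000 / X` where `X` is a (truncated) normal rate draw. Rate
#' means increase linearly with age so older subjects respond faster; per
#' subject, means and SDs are jittered to create realistic between-subject
#' variability. `rho` is the within-trial correlation of the two channel
#' rates on AV trials, `eta` inflates both channel SDs by `(1 + eta)` on AV
#' trials, and `switch_cost` (1/s) is subtracted from a channel's rate mean
#' when the preceding trial did not contain that channel's modality.
#'
#' Group effects for the ASD group: `asd_mu_shift` (rate decrement, slower
#' responses), `asd_rho_shift` (more positive channel coupling), both applied
#' only below `asd_shift_max_age`; `asd_age_lag` makes ASD parameters those
#' of a subject `lag` years younger (a developmental delay).
#'
#' @param n_nt,n_asd Subjects per group (must be > 0).
#' @param age_range Years, `c(min, max)`.
#' @param n_blocks,block_size Trials are generated in `n_blocks` blocks of
#'   `block_size` trials.
#' @param isi_range_ms Uniform ISI range in ms.
#' @param mu_base Named rate means (1/s) at the youngest age, `c(A=, V=)`.
#' @param mu_age_slope Rate increase per year (1/s).
#' @param sigma_base Named rate SDs (1/s).
#' @param mu_jitter_sd,sigma_jitter_sd Between-subject SD of the per-subject
#'   jitter added to rate means / SDs.
#' @param dominance_jitter_sd Between-subject SD of the sensory-dominance
#'   asymmetry: a zero-mean draw added to the auditory rate mean and
#'   subtracted from the visual one, so subjects differ in which modality
#'   is the faster channel (individual differences in sensory dominance).
#' @param rho_base,rho_age_slope Channel correlation at the youngest age and
#'   its change per year (clamped to `[-0.9, 0.9]`).
#' @param eta_base,eta_age_slope Multisensory noise inflation (>= 0).
#' @param switch_cost Rate decrement (1/s) on switch trials.
#' @param switch_cost_isi_tau Exponential decay constant (ms) of the switch
#'   cost with preceding ISI; `Inf` (default) means no decay.
#' @param asd_mu_shift,asd_rho_shift,asd_shift_max_age,asd_age_lag Group
#'   effects, see Details.
#' @param competition_mode One of `"none"`, `"model1A"`, `"model1V"`,
#'   `"model2A"`, `"model2V"`.
#' @param p_competition Probability that an AV response is triggered by the
#'   biased channel rather than the race.
#' @param miss_rate,fa_rate Miss probability per trial and false-alarm rate
#'   (FAs are summarised as a per-subject count, not trial records).
#' @param seed Integer root seed; all stages derive named substreams from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nt = 20L, n_asd = 20L,
                          age_range = c(6, 40),
                          n_blocks = 8L, block_size = 100L,
                          isi_range_ms = c(1000, 3000),
                          mu_base = c(A = 1.95, V = 1.80),
                          mu_age_slope = 0.045,
                          sigma_base = c(A = 0.55, V = 0.55),
                          mu_jitter_sd = 0.22,
                          dominance_jitter_sd = 0.25,
                          sigma_jitter_sd = 0.08,
                          rho_base = 0.15, rho_age_slope = -0.012,
                          eta_base = 0.05, eta_age_slope = 0.004,
                          switch_cost = 0.18,
                          switch_cost_isi_tau = Inf,
                          asd_mu_shift = -0.12,
                          asd_rho_shift = 0.25,
                          asd_shift_max_age = 18,
                          asd_age_lag = 0,
                          competition_mode = c("none", "model1A", "model1V",
                                               "model2A", "model2V"),
                          p_competition = 0,
                          miss_rate = 0.05, fa_rate = 0.03,
                          seed = 1L) {
  competition_mode <- match.arg(competition_mode)
  if (n_nt <= 0 || n_asd <= 0) stop_invalid("both groups must be non-empty")
  if (length(isi_range_ms) != 2 || any(isi_range_ms <= 0) ||
      isi_range_ms[1] >= isi_range_ms[2]) {
    stop_invalid("isi_range_ms must be a positive (min, max) with min < max")
  }
  for (p in c(p_competition, miss_rate, fa_rate)) {
    if (p < 0 || p > 1) stop_invalid("probabilities must lie in [0, 1]")
  }
  if (any(sigma_base <= 0)) stop_invalid("rate SDs must be positive")
  if (switch_cost < 0 || eta_base < 0) {
    stop_invalid("switch_cost and eta must be non-negative")
  }
  if (abs(rho_base) > 1) stop_invalid("rho must lie in [-1, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

## Resolve subject-level generating parameters from group and age.
## Jitter (if any) must be drawn by the caller under its own substream.
subject_params <- function(cfg, group, age,
                           mu_jitter = c(A = 0, V = 0),
                           sigma_jitter = c(A = 0, V = 0)) {
  eff_age <- age
  if (group == "ASD") eff_age <- age - cfg$asd_age_lag
  a0 <- cfg$age_range[1]
  mu <- cfg$mu_base + cfg$mu_age_slope * (eff_age - a0) + mu_jitter
  sigma <- pmax(cfg$sigma_base + sigma_jitter, 0.1)
  rho <- cfg$rho_base + cfg$rho_age_slope * (eff_age - a0)
  eta <- max(0, cfg$eta_base + cfg$eta_age_slope * (eff_age - a0))
  if (group == "ASD" && age < cfg$asd_shift_max_age) {
    mu <- mu + cfg$asd_mu_shift
    rho <- rho + cfg$asd_rho_shift
  }
  list(mu = pmax(mu, 0.3), sigma = sigma,
       rho = max(-0.9, min(0.9, rho)), eta = eta,
       switch_cost = cfg$switch_cost,
       switch_cost_isi_tau = cfg$switch_cost_isi_tau,
       competition_mode = cfg$competition_mode,
       p_competition = cfg$p_competition,
       miss_rate = cfg$miss_rate)
}

#' Sample a randomised stimulus sequence
#'
#' Conditions are drawn i.i.d. with equal probability from A, V and AV, and
#' ISIs i.i.d. uniform on the configured range, emulating a completely
#' randomised interleaved design.
#'
#' @param n Number of trials (> 0).
#' @param cfg Optional [cohort_config()]; only the ISI range is used.
#' @param seed Optional seed for reproducibility.
#' @return A data frame with columns `condition` and `isi_ms`.
#' @export
sample_trial_sequence <- function(n, cfg = NULL, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n <= 0) stop_invalid("n must be positive")
  isi <- if (is.null(cfg)) c(1000, 3000) else cfg$isi_range_ms
  with_seed(seed, data.frame(
    condition = sample(CONDITIONS, n, replace = TRUE),
    isi_ms = stats::runif(n, isi[1], isi[2])
  ))
}

#' Probability that the next trial contains the same unisensory component
#'
#' Exact enumeration over the 3 x 3 transition structure of an equiprobable
#' A/V/AV design: given that the current trial contains a particular
#' unisensory component (alone or within AV), the next trial contains that
#' same component whenever it is that unisensory condition or AV, i.e. with
#' probability 2/3 (about 66.6%).
#'
#' @return A single probability.
#' @export
same_component_next_prob <- function() {
  contains <- list(A = "A", V = "V", AV = c("A", "V"))
  num <- 0; den <- 0
  for (cur in CONDITIONS) {
    for (comp in contains[[cur]]) {
      for (nxt in CONDITIONS) {
        den <- den + 1 / 9
        if (comp %in% contains[[nxt]]) num <- num + 1 / 9
      }
    }
  }
  num / den
}

## Draw correlated channel rates for one batch of trials (vectorised).
draw_rates <- function(n, mu_a, mu_v, s_a, s_v, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  list(a = mu_a + s_a * z1,
       v = mu_v + s_v * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Generate single-subject trial records
#'
#' Unisensory RTs are `1000 / X` with `X ~ N(mu_c - switch penalty, sigma_c)`
#' truncated to `X > 0` by rejection. AV RTs are `1000 / max(X_A, X_V)` with
#' the two rates correlated at `rho` and SDs inflated by `(1 + eta)`, except
#' in a competition mode where, with probability `p_competition`, the
#' response is drawn solely from the biased channel dictated by the mode.
#' The switch penalty is applied per channel: a channel's rate mean is
#' reduced by `switch_cost` when the preceding trial did not contain that
#' channel's modality (so AV trials are only penalised on their "switched"
#' channel). Misses are encoded as absent `rt_ms` with `n_presses = 0`.
#'
#' @param params Subject-level parameter list as built by the cohort
#'   generator: `mu`, `sigma` (named A/V, 1/s), `rho`, `eta`, `switch_cost`,
#'   `switch_cost_isi_tau`, `competition_mode`, `p_competition`, `miss_rate`.
#' @param sequence Data frame with `condition` and `isi_ms` (from
#'   [sample_trial_sequence()]).
#' @param seed Optional seed.
#' @param block_size Trials per block for block/trial indexing.
#' @return A data frame of trial records: `block`, `trial_idx`, `condition`,
#'   `isi_ms`, `rt_ms` (NA = miss), `n_presses`.
#' @export
generate_subject_trials <- function(params, sequence, seed = NULL,
                                    block_size = 100L) {
  if (nrow(sequence) == 0) stop_invalid("sequence must be non-empty")
  if (any(params$mu <= 0) || any(params$sigma <= 0)) {
    stop_invalid("channel rates must be positive")
  }
  with_seed(seed, {
    n <- nrow(sequence)
    cond <- sequence$condition
    isi <- sequence$isi_ms
    block <- (seq_len(n) - 1L) %/% block_size + 1L
    trial_idx <- (seq_len(n) - 1L) %% block_size + 1L

    prev <- c(NA, cond[-n])
    prev[trial_idx == 1L] <- NA  # switch state resets at block boundaries

    ## per-channel switch penalties (optionally decaying with preceding ISI)
    decay <- if (is.finite(params$switch_cost_isi_tau)) {
      exp(-(isi - 1000) / params$switch_cost_isi_tau)
    } else 1
    pen_a <- params$switch_cost * decay * (!is.na(prev) & prev == "V")
    pen_v <- params$switch_cost * decay * (!is.na(prev) & prev == "A")

    infl <- 1 + params$eta * (cond == "AV")
    mu_a <- params$mu[["A"]] - pen_a
    mu_v <- params$mu[["V"]] - pen_v
    s_a <- params$sigma[["A"]] * infl
    s_v <- params$sigma[["V"]] * infl

    ## competition: which channel (if any) triggers the AV response
    forced <- rep(NA_character_, n)
    if (params$competition_mode != "none" && params$p_competition > 0) {
      comp <- cond == "AV" & stats::runif(n) < params$p_competition
      bias <- substr(params$competition_mode, 7, 7)  # terminal A or V
      if (params$competition_mode %in% c("model1A", "model1V")) {
        forced[comp] <- bias
      } else {  # model2: previous modality; bias when preceded by AV or none
        f <- ifelse(is.na(prev) | prev == "AV", bias,
                    ifelse(prev == "A", "A", "V"))
        forced[comp] <- f[comp]
      }
    }

    rates <- draw_rates(n, mu_a, mu_v, s_a, s_v, params$rho)
    used <- function(r) {
      x <- numeric(n)
      x[cond == "A"] <- r$a[cond == "A"]
      x[cond == "V"] <- r$v[cond == "V"]
      av <- cond == "AV"
      x[av] <- pmax(r$a[av], r$v[av])
      f <- !is.na(forced)
      x[f & forced == "A"] <- r$a[f & forced == "A"]
      x[f & forced == "V"] <- r$v[f & forced == "V"]
      x
    }
    x <- used(rates)
    while (any(bad <- x <= 0)) {  # rejection: keep the triggering rate positive
      k <- which(bad)
      r2 <- draw_rates(length(k), mu_a[k], mu_v[k], s_a[k], s_v[k], params$rho)
      rates$a[k] <- r2$a; rates$v[k] <- r2$v
      x <- used(rates)
    }

    rt <- 1000 / x
    miss <- stats::runif(n) < params$miss_rate
    rt[miss] <- NA_real_
    data.frame(block = block, trial_idx = trial_idx, condition = cond,
               isi_ms = isi, rt_ms = rt,
               n_presses = as.integer(!miss), stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' Samples subject demographics (age uniform over the configured range, sex,
#' performance/verbal/full-scale IQ), resolves per-subject generating
#' parameters from group and age (with between-subject jitter), and
#' generates each subject's trial table. All randomness derives from the
#' config seed through named substreams, so two runs with the same config
#' are identical.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `subjects` (one row per subject, including generator
#'   ground-truth columns `true_*`) and `trials` (stacked trial records).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_nt + cfg$n_asd
  group <- rep(c("NT", "ASD"), c(cfg$n_nt, cfg$n_asd))
  id <- sprintf("S%03d", seq_len(n))
  n_trials <- cfg$n_blocks * cfg$block_size

  subjects <- with_seed(stage_seed(cfg$seed, "subjects"), {
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    data.frame(
      subject_id = id, group = group, age_years = round(age, 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      piq = round(pmax(80, stats::rnorm(n, 107, 13))),
      viq = round(pmax(55, stats::rnorm(n, 108, 15))),
      fsiq = round(pmax(60, stats::rnorm(n, 108, 14))),
      fa_count = stats::rbinom(n, n_trials, cfg$fa_rate),
      stringsAsFactors = FALSE
    )
  })

  params <- vector("list", n)
  subjects$true_mu_a <- subjects$true_mu_v <- NA_real_
  subjects$true_sigma_a <- subjects$true_sigma_v <- NA_real_
  subjects$true_rho <- subjects$true_eta <- NA_real_
  for (i in seq_len(n)) {
    jit <- with_seed(stage_seed(cfg$seed, paste0("params_", id[i])), list(
      mu = stats::rnorm(2, 0, cfg$mu_jitter_sd),
      dom = stats::rnorm(1, 0, cfg$dominance_jitter_sd),
      sigma = stats::rnorm(2, 0, cfg$sigma_jitter_sd)
    ))
    p <- subject_params(cfg, group[i], subjects$age_years[i],
                        mu_jitter = c(A = jit$mu[1] + jit$dom,
                                      V = jit$mu[2] - jit$dom),
                        sigma_jitter = c(A = jit$sigma[1], V = jit$sigma[2]))
    params[[i]] <- p
    subjects$true_mu_a[i] <- p$mu[["A"]]; subjects$true_mu_v[i] <- p$mu[["V"]]
    subjects$true_sigma_a[i] <- p$sigma[["A"]]
    subjects$true_sigma_v[i] <- p$sigma[["V"]]
    subjects$true_rho[i] <- p$rho; subjects$true_eta[i] <- p$eta
  }

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    seq_i <- sample_trial_sequence(n_trials, cfg,
                                   seed = stage_seed(cfg$seed, paste0("seq_", id[i])))
    tr <- generate_subject_trials(params[[i]], seq_i,
                                  seed = stage_seed(cfg$seed, paste0("trials_", id[i])),
                                  block_size = cfg$block_size)
    tr$subject_id <- id[i]
    trials[[i]] <- tr[, c("subject_id", "block", "trial_idx", "condition",
                          "isi_ms", "rt_ms", "n_presses")]
  }
  list(subjects = subjects, trials = do.call(rbind, trials))
}
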