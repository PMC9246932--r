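# Fixtures are built in code at test time; nothing is stored on disk.

# Subject-level generating parameters without group/age machinery.
base_params <- function(mu_a = 3, mu_v = 2.8, sigma_a = 0.6, sigma_v = 0.55,
                        rho = 0, eta = 0, switch_cost = 0,
                        switch_cost_isi_tau = Inf,
                        competition_mode = "none", p_competition = 0,
                        miss_rate = 0) {
  list(mu = c(A = mu_a, V = mu_v), sigma = c(A = sigma_a, V = sigma_v),
       rho = rho, eta = eta, switch_cost = switch_cost,
       switch_cost_isi_tau = switch_cost_isi_tau,
       competition_mode = competition_mode, p_competition = p_competition,
       miss_rate = miss_rate)
}

# One synthetic subject's trial table.
make_subject <- function(n = 800, seed = 1, params = base_params(), ...) {
  params <- utils::modifyList(params, list(...))
  sq <- sample_trial_sequence(n, seed = seed)
  generate_subject_trials(params, sq, seed = seed + 10000L)
}

# Minimal hand-built trial table (valid RTs unless rt is NA).
manual_trials <- function(condition, rt, block = 1L,
                          trial_idx = seq_along(condition) + 3L,
                          isi = 2000) {
  data.frame(block = block, trial_idx = trial_idx, condition = condition,
             isi_ms = isi, rt_ms = rt,
             n_presses = as.integer(!is.na(rt)), stringsAsFactors = FALSE)
}

# A fabricated cdf_set with identical CDFs in every stratum (for collapse
# and symmetry checks of the bias/race models).
flat_cdfset <- function(probs_a, probs_v, probs_av,
                        times = seq(200, 600, length.out = length(probs_a))) {
  mk <- function(p) quantile_cdf(p, times)
  same <- function(p) {
    l <- lapply(c(A = "A", V = "V", AV = "AV"), function(m) mk(p))
    l
  }
  structure(list(
    cdf = list(A = mk(probs_a), V = mk(probs_v), AV = mk(probs_av)),
    by_prev = list(A = same(probs_a), V = same(probs_v), AV = same(probs_av)),
    switch = list(A = NULL, V = NULL, AV = NULL),
    repeat_ = list(A = NULL, V = NULL, AV = NULL),
    av_switch_from = list(A = NULL, V = NULL),
    limits = c(times[1], times[length(times)]),
    eval_times_ms = times, n_q = length(times), min_n = 5L,
    n = c(A = 100L, V = 100L, AV = 100L)
  ), class = "cdf_set")
}
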