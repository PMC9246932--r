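## LATER channel fits and the correlated-channel (rho, eta) race model -------
##
## The LATER framework treats the reciprocal of RT (a processing rate, 1/s
## when RT is in ms and scaled by 1000) as normally distributed. The
## context-variant race model predicts the multisensory RT as
## 1000 / max(X_A, X_V) with (X_A, X_V) bivariate normal: channel SDs
## inflated multiplicatively by (1 + eta) and correlated at rho. rho and eta
## are the only free parameters; the channel means/SDs are fixed from the
## unisensory fits.

#' Fit the LATER reciprocal-normal model to one RT sample
#'
#' Maximum-likelihood normal fit to the rates `1000 / RT` (1/s): `mu` is
#' the sample mean and `sigma` the ML (1/n) standard deviation.
#'
#' @param rts_ms RT sample in ms, all positive, at least 20 values.
#' @param min_n Minimum sample size.
#' @return A list: `mu`, `sigma`, `n`, `degenerate` (TRUE when sigma ~ 0).
#' @export
fit_later <- function(rts_ms, min_n = 20L) {
  rts_ms <- rts_ms[!is.na(rts_ms)]
  if (length(rts_ms) < min_n) stop_invalid("need at least %d RTs", min_n)
  if (any(rts_ms <= 0)) stop_invalid("RTs must be positive")
  x <- 1000 / rts_ms
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  list(mu = mu, sigma = sigma, n = length(x),
       degenerate = sigma < 1e-8 * max(abs(mu), 1))
}

## Density of max(X_A, X_V) for bivariate normal channels (closed form:
## the sum of two skew-weighted normal terms).
max_rate_density <- function(z, mu_a, sig_a, mu_v, sig_v, rho) {
  za <- (z - mu_a) / sig_a
  zv <- (z - mu_v) / sig_v
  if (abs(rho) >= 1) {
    ## degenerate coupling: max of two perfectly (anti)correlated normals
    rho <- sign(rho) * (1 - 1e-10)
  }
  s <- sqrt(1 - rho^2)
  ## f_X(z) P(Y <= z | X = z) + f_Y(z) P(X <= z | Y = z)
  stats::dnorm(za) / sig_a * stats::pnorm((zv - rho * za) / s) +
    stats::dnorm(zv) / sig_v * stats::pnorm((za - rho * zv) / s)
}

## P(X_A <= z, X_V <= z): one-dimensional reduction of the bivariate normal
## CDF, integrated with Gauss-Legendre quadrature.
max_rate_cdf <- function(z, mu_a, sig_a, mu_v, sig_v, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-10)
  s <- sqrt(1 - rho^2)
  gl <- gauss_legendre(96)
  vapply(z, function(zz) {
    za <- (zz - mu_a) / sig_a
    zv <- (zz - mu_v) / sig_v
    lo <- -8.5
    if (za <= lo) return(0)
    u <- (za + lo) / 2 + (za - lo) / 2 * gl$nodes
    w <- (za - lo) / 2 * gl$weights
    sum(w * stats::dnorm(u) * stats::pnorm((zv - rho * u) / s))
  }, numeric(1))
}

## Fixed Gauss-Legendre rule on [-1, 1] (Golub-Welsch), cached.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(nodes = rev(e$values),
                weights = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- res
    res
  }
})

#' Predicted multisensory RT distribution under the context-variant race
#'
#' CDF of `RT = 1000 / max(X_A, X_V)` at the requested latencies, with the
#' two channel rates bivariate normal: means/SDs from the unisensory LATER
#' fits, SDs inflated by `(1 + eta)`, correlation `rho`.
#' `P(RT <= t) = 1 - P(X_A <= 1000/t, X_V <= 1000/t)`.
#'
#' @param fit A list with `mu_a`, `sigma_a`, `mu_v`, `sigma_v`, `rho`,
#'   `eta` (as returned by [fit_context_race()]).
#' @param eval_times_ms Latencies (ms) at which to evaluate the CDF.
#' @return A [quantile_cdf()].
#' @export
predict_av_distribution <- function(fit, eval_times_ms) {
  if (abs(fit$rho) > 1 || fit$eta < 0) stop_invalid("invalid rho or eta")
  infl <- 1 + fit$eta
  z <- 1000 / eval_times_ms
  probs <- 1 - max_rate_cdf(z, fit$mu_a, fit$sigma_a * infl,
                            fit$mu_v, fit$sigma_v * infl, fit$rho)
  quantile_cdf(probs, eval_times_ms)
}

## Negative log-likelihood of AV RTs under the max-rate model.
context_race_nll <- function(par, rate_av, mu_a, sig_a, mu_v, sig_v) {
  rho <- par[1]; eta <- par[2]
  infl <- 1 + eta
  d <- max_rate_density(rate_av, mu_a, sig_a * infl, mu_v, sig_v * infl, rho)
  -sum(log(pmax(d, 1e-300)))
}

#' Fit the context-variant race model to one subject
#'
#' LATER channel parameters are fixed from the unisensory samples; `rho`
#' (channel correlation) and `eta` (multiplicative SD inflation) are chosen
#' to maximise the likelihood of the observed multisensory RTs under the
#' max-rate model, by bounded quasi-Newton search from 5 deterministic
#' starts. The density is evaluated on the rate scale (the 1000/t Jacobian
#' is parameter-free and drops out of the optimisation).
#'
#' @param rts_a,rts_v,rts_av RT samples (ms) for the three conditions.
#' @param min_n Minimum RTs per condition.
#' @param rho_bounds,eta_bounds Box constraints for the search.
#' @return A list of class `context_race_fit`: `mu_a`, `sigma_a`, `mu_v`,
#'   `sigma_v`, `rho`, `eta`, `objective` (minimised negative
#'   log-likelihood), `converged`, `n_av`.
#' @export
fit_context_race <- function(rts_a, rts_v, rts_av, min_n = 20L,
                             rho_bounds = c(-0.95, 0.95),
                             eta_bounds = c(0, 2)) {
  fa <- fit_later(rts_a, min_n)
  fv <- fit_later(rts_v, min_n)
  rts_av <- rts_av[!is.na(rts_av)]
  if (length(rts_av) < min_n) stop_invalid("need at least %d AV RTs", min_n)
  rate_av <- 1000 / rts_av

  starts <- rbind(c(0, 0.05), c(-0.5, 0.1), c(0.5, 0.1),
                  c(-0.2, 0.4), c(0.2, 0.4))
  best <- NULL
  converged <- FALSE
  for (k in seq_len(nrow(starts))) {
    o <- try(stats::optim(starts[k, ], context_race_nll,
                          rate_av = rate_av, mu_a = fa$mu, sig_a = fa$sigma,
                          mu_v = fv$mu, sig_v = fv$sigma,
                          method = "L-BFGS-B",
                          lower = c(rho_bounds[1], eta_bounds[1]),
                          upper = c(rho_bounds[2], eta_bounds[2])),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop_invalid("context-race optimisation failed")
  structure(list(mu_a = fa$mu, sigma_a = fa$sigma,
                 mu_v = fv$mu, sigma_v = fv$sigma,
                 rho = unname(best$par[1]), eta = unname(best$par[2]),
                 objective = best$value, converged = converged,
                 n_av = length(rts_av)),
            class = "context_race_fit")
}

#' Switch/repeat frequency per RT quantile
#'
#' For the unisensory trials of one subject, counts switch and repeat
#' trials within each quantile bin of the shared evaluation grid. With a
#' positive switch cost, switch trials are over-represented in the slow
#' quantiles, visualising the negative channel dependency.
#'
#' @param trials One subject's trial records.
#' @param n_q Number of quantile bins.
#' @return A data frame: `quantile`, `t_lo_ms`, `t_hi_ms`, `n_switch`,
#'   `n_repeat`.
#' @export
switch_repeat_frequency_profile <- function(trials, n_q = 20L) {
  if (is.null(trials$rt_valid)) trials <- clean_rts(trials)
  tr <- annotate_sequence(trials)
  cl <- tr[tr$rt_valid & tr$condition %in% c("A", "V") &
             !is.na(tr$transition), , drop = FALSE]
  if (nrow(cl) == 0) {
    return(data.frame(quantile = integer(0), t_lo_ms = numeric(0),
                      t_hi_ms = numeric(0), n_switch = integer(0),
                      n_repeat = integer(0)))
  }
  edges <- seq(min(cl$rt_ms), max(cl$rt_ms), length.out = n_q + 1)
  bin <- findInterval(cl$rt_ms, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(
    quantile = seq_len(n_q),
    t_lo_ms = edges[-(n_q + 1)], t_hi_ms = edges[-1],
    n_switch = vapply(seq_len(n_q), function(b) {
      sum(bin == b & cl$transition == "switch")
    }, numeric(1)),
    n_repeat = vapply(seq_len(n_q), function(b) {
      sum(bin == b & cl$transition == "repeat")
    }, numeric(1))
  )
}
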