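## Nonparametric inference: permutation tests, BCa bootstrap, effect sizes,
## Bayes factors, rank-based inverse normal transform -------------------------

#' Permutation tests with max-statistic or FDR correction
#'
#' One-sample/paired tests permute by flipping signs; two-sample tests
#' permute group labels. The test statistic is Student's t per variable
#' (column). Multivariate inputs can be corrected for multiple comparisons
#' using the permutation distribution of the maximum statistic (`tmax`,
#' family-wise error control) or Benjamini-Hochberg FDR. p-values use the
#' add-one estimator `p = (1 + #{perm >= obs}) / (n_perm + 1)` and can
#' never be zero.
#'
#' @param x Numeric vector or matrix (observations x variables).
#' @param y Optional second sample (two-sample test) or, with
#'   `paired = TRUE`, the paired companion of `x`.
#' @param tail `"right"`, `"left"` or `"both"` (two-tailed).
#' @param n_perm Number of permutations (>= 1).
#' @param correction `"tmax"`, `"fdr"` or `"none"`.
#' @param paired Treat `x` and `y` as paired and test `x - y`.
#' @param seed Optional seed.
#' @return A list: `statistic` (per variable), `p` (corrected as
#'   requested), `p_uncorrected`, `correction`, `tail`, `n_perm`.
#' @export
permutation_test <- function(x, y = NULL, tail = c("both", "right", "left"),
                             n_perm = 10000L, correction = c("tmax", "fdr", "none"),
                             paired = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  correction <- match.arg(correction)
  if (n_perm < 1) stop_invalid("n_perm must be at least 1")
  x <- as.matrix(x)
  if (!is.null(y)) y <- as.matrix(y)
  if (paired) {
    if (is.null(y) || !all(dim(x) == dim(y))) {
      stop_invalid("paired test needs equal-size x and y")
    }
    x <- x - y
    y <- NULL
  }

  with_seed(seed, {
    if (is.null(y)) {
      n <- nrow(x)
      if (n < 2) stop_invalid("need at least 2 observations")
      ss <- colSums(x^2)
      t_of <- function(m) {
        v <- (rep(ss, each = nrow(m)) - n * m^2) / (n - 1)
        m / sqrt(pmax(v, 1e-300) / n)
      }
      t_obs <- drop(t_of(matrix(colMeans(x), nrow = 1)))
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      t_perm <- t_of(S %*% x / n)
    } else {
      if (ncol(x) != ncol(y)) stop_invalid("x and y need matching variables")
      n1 <- nrow(x); n2 <- nrow(y); n <- n1 + n2
      if (n1 < 2 || n2 < 2) stop_invalid("need at least 2 observations per group")
      z <- rbind(x, y)
      tot <- colSums(z)
      ssq <- colSums(z^2)
      df <- n - 2
      t_of <- function(s1) {  # s1: per-permutation group-1 column sums
        m1 <- s1 / n1
        m2 <- (rep(tot, each = nrow(s1)) - s1) / n2
        sp2 <- (rep(ssq, each = nrow(s1)) - n1 * m1^2 - n2 * m2^2) / df
        (m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2))
      }
      t_obs <- drop(t_of(matrix(colSums(x), nrow = 1)))
      P <- matrix(0, n_perm, n)
      for (b in seq_len(n_perm)) P[b, sample.int(n, n1)] <- 1
      t_perm <- t_of(P %*% z)
    }

    score <- switch(tail,
                    right = function(t) t,
                    left = function(t) -t,
                    both = function(t) abs(t))
    s_obs <- score(t_obs)
    s_perm <- score(t_perm)
    q <- length(t_obs)
    p_unc <- vapply(seq_len(q), function(j) {
      (1 + sum(s_perm[, j] >= s_obs[j])) / (n_perm + 1)
    }, numeric(1))
    p <- switch(correction,
      none = p_unc,
      fdr = stats::p.adjust(p_unc, "BH"),
      tmax = {
        mx <- apply(s_perm, 1, max)
        vapply(s_obs, function(s) (1 + sum(mx >= s)) / (n_perm + 1), numeric(1))
      })
    list(statistic = t_obs, p = p, p_uncorrected = p_unc,
         correction = correction, tail = tail, n_perm = n_perm)
  })
}

## Two-tailed permutation p for a Pearson correlation (pairings permuted).
cor_permutation_p <- function(x, y, n_perm = 10000L, seed = NULL) {
  with_seed(seed, {
    r_obs <- abs(stats::cor(x, y))
    r_perm <- vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(x, y[sample.int(length(y))]))
    }, numeric(1))
    (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  })
}

## BCa interval from precomputed bootstrap and jackknife statistics.
bca_interval <- function(est, boot, jack, level = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) == 0) return(c(NA_real_, NA_real_))
  if (max(boot) - min(boot) < 1e-15) return(c(est, est))
  prop <- (sum(boot < est) + 0.5 * sum(boot == est)) / length(boot)
  prop <- min(max(prop, 1 / (length(boot) + 1)), length(boot) / (length(boot) + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom < 1e-300) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zal <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  unname(stats::quantile(boot, adj, names = FALSE, type = 7))
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap of an arbitrary statistic with the BCa
#' adjustment: bias correction from the bootstrap distribution's position
#' relative to the estimate, acceleration from the jackknife. With zero
#' bias and acceleration it reduces to the percentile interval.
#'
#' @param values Numeric vector of observations (>= 3).
#' @param statistic_fn Function of a numeric vector returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional seed.
#' @return A list: `estimate`, `ci` (`c(lo, hi)`), `se` (bootstrap SD),
#'   `n_boot`, `level`.
#' @export
bootstrap_ci <- function(values, statistic_fn = mean, n_boot = 10000L,
                         level = 0.95, seed = NULL) {
  n <- length(values)
  if (n < 3) stop_invalid("need at least 3 observations")
  with_seed(seed, {
    est <- statistic_fn(values)
    boot <- vapply(seq_len(n_boot), function(b) {
      statistic_fn(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    bad <- !is.finite(boot)
    tries <- 0
    while (any(bad) && tries < 50) {  # statistic undefined on a resample: redraw
      idx <- which(bad)
      boot[idx] <- vapply(idx, function(b) {
        statistic_fn(values[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
      bad <- !is.finite(boot)
      tries <- tries + 1
    }
    jack <- vapply(seq_len(n), function(i) statistic_fn(values[-i]), numeric(1))
    list(estimate = est, ci = bca_interval(est, boot, jack, level),
         se = stats::sd(boot), n_boot = n_boot, level = level)
  })
}

#' Hedge's g with a BCa-bootstrapped confidence interval
#'
#' Pooled-SD standardised mean difference with the exact small-sample bias
#' correction `J(df) = Gamma(df/2) / (sqrt(df/2) Gamma((df-1)/2))`.
#'
#' @param x,y Samples (>= 2 each).
#' @param n_boot Bootstrap resamples for the CI (0 skips the CI).
#' @param level Confidence level.
#' @param seed Optional seed.
#' @return A list: `g`, `ci`, `undefined` (TRUE when the pooled SD is 0).
#' @export
hedges_g <- function(x, y, n_boot = 10000L, level = 0.95, seed = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_invalid("need at least 2 observations per sample")
  g_of <- function(x, y) {
    df <- length(x) + length(y) - 2
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) / df)
    if (sp < 1e-300) return(NA_real_)
    j <- exp(lgamma(df / 2) - 0.5 * log(df / 2) - lgamma((df - 1) / 2))
    j * (mean(x) - mean(y)) / sp
  }
  g <- g_of(x, y)
  if (is.na(g)) {
    return(list(g = NA_real_, ci = c(NA_real_, NA_real_), undefined = TRUE))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      boot <- vapply(seq_len(n_boot), function(b) {
        g_of(x[sample.int(n1, n1, replace = TRUE)],
             y[sample.int(n2, n2, replace = TRUE)])
      }, numeric(1))
      jack <- c(vapply(seq_len(n1), function(i) g_of(x[-i], y), numeric(1)),
                vapply(seq_len(n2), function(i) g_of(x, y[-i]), numeric(1)))
      bca_interval(g, boot[is.finite(boot)], jack[is.finite(jack)], level)
    })
  }
  list(g = g, ci = ci, undefined = FALSE)
}

#' JZS Bayes factor in favour of the null (BF01)
#'
#' Default-prior Bayes factor for a t statistic: the standardised effect is
#' given a Cauchy prior (scale `prior_scale`), equivalently a normal prior
#' with variance `g * prior_scale^2` mixed over an inverse-chi-square(1)
#' distribution on `g`; the marginal likelihood ratio is computed by
#' numerical integration over `g`. Works for one-sample (`n2 = NULL`),
#' two-sample, and regression-term t statistics (pass the residual df via
#' `df` and the number of observations via `n1`).
#'
#' @param t Observed t statistic.
#' @param n1,n2 Sample sizes.
#' @param df Degrees of freedom; defaults to `n1 - 1` (one-sample) or
#'   `n1 + n2 - 2` (two-sample).
#' @param prior_scale Cauchy prior scale (default 1).
#' @return BF01 (evidence for the null; > 1 favours the null).
#' @export
bayes_factor_t <- function(t, n1, n2 = NULL, df = NULL, prior_scale = 1) {
  N <- if (is.null(n2)) n1 else n1 * n2 / (n1 + n2)
  if (is.null(df)) df <- if (is.null(n2)) n1 - 1 else n1 + n2 - 2
  r <- prior_scale
  null_lik <- (1 + t^2 / df)^(-(df + 1) / 2)
  integrand <- function(u) {
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    dens <- r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
    lik <- (1 + N * g)^(-0.5) *
      (1 + t^2 / ((1 + N * g) * df))^(-(df + 1) / 2)
    lik * dens * jac
  }
  alt_lik <- tryCatch(
    stats::integrate(integrand, 0, 1, rel.tol = 1e-8,
                     stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (!is.finite(alt_lik) || alt_lik <= 0) {
    warning("Bayes factor integration failed")
    return(NA_real_)
  }
  null_lik / alt_lik
}

#' Rank-based inverse normal (RIN) transform
#'
#' Rankit transform `qnorm((rank - 0.5) / n)` with mid-ranks for ties;
#' preserves rank order and maps the sample onto approximate normal scores.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return The transformed vector.
#' @export
rin_transform <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2) stop_invalid("all values tied")
  n <- sum(!is.na(x))
  out <- rep(NA_real_, length(x))
  out[!is.na(x)] <- stats::qnorm((rank(x[!is.na(x)], ties.method = "average") - 0.5) / n)
  out
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the covariate; significance by a two-tailed permutation test of
#' the residual pairings.
#'
#' @param x,y,covariate Numeric vectors of equal length (>= 4).
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Optional seed.
#' @return A list: `r`, `p_perm`.
#' @export
partial_correlation <- function(x, y, covariate, n_perm = 10000L, seed = NULL) {
  n <- length(x)
  if (n < 4 || length(y) != n || length(covariate) != n) {
    stop_invalid("need equal-length inputs with n >= 4")
  }
  ## a constant covariate carries no variance: plain residuals about the mean
  rx <- stats::resid(stats::lm(x ~ covariate))
  ry <- stats::resid(stats::lm(y ~ covariate))
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14) {
    warning("constant residuals: partial correlation undefined")
    return(list(r = NA_real_, p_perm = NA_real_))
  }
  r <- stats::cor(rx, ry)
  p <- if (n_perm > 0) cor_permutation_p(rx, ry, n_perm, seed) else NA_real_
  list(r = r, p_perm = p)
}
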