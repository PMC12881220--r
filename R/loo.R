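# Pareto-smoothed importance sampling leave-one-out cross-validation.
# The generalized Pareto tail fit uses the Zhang & Stephens (2009)
# profile-posterior estimator.

# Fit a generalized Pareto distribution to exceedances x (> 0).
# Returns shape k and scale sigma.
fit_gpd <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[floor(n / 4 + 0.5)])
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), 0)
  L <- n * (log(bs / ks) + ks - 1)
  L[!is.finite(L)] <- -Inf
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(L - L[i])), 0)
  w[!is.finite(w)] <- 0
  b <- sum(bs * w) / sum(w)
  k_zs <- -mean(log1p(-b * x))
  # convert to the usual tail-shape convention (xi > 0: heavy tail)
  list(k = -k_zs, sigma = k_zs / b)
}

# Pareto-smooth one vector of log importance ratios.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  ntail <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (ntail < 5) return(list(lw = lw, k = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - ntail + 1):S]
  cutoff <- lw[ord[S - ntail]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  fit <- fit_gpd(exc[exc > 0])
  if (is.finite(fit$k) && !is.na(fit$sigma) && fit$sigma > 0) {
    # replace tail by expected order statistics of the fitted GPD
    p <- (seq_len(ntail) - 0.5) / ntail
    qgpd <- if (abs(fit$k) < 1e-12) -fit$sigma * log1p(-p) else
      fit$sigma * expm1(-fit$k * log1p(-p)) / fit$k
    smoothed <- log(exp(cutoff) + qgpd)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  lw <- pmin(lw, 0)        # truncate at the raw maximum (scaled to 0)
  list(lw = lw - logsumexp(lw), k = fit$k)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pointwise conditional log-likelihood matrix (draws x observations):
# p(y_i | beta_s, u_s, sigma_e_s) with random effects drawn from their
# conditional posterior, the pointwise definition used for LOO.
pointwise_loglik <- function(fit, max_draws = 400) {
  re <- draw_random_effects(fit, max_draws)
  idx <- re$idx
  dat <- fit$data
  mu_fix <- fit$draws[idx, 1:2, drop = FALSE] %*% t(dat$X)
  mu <- mu_fix + re$fitted_re
  se <- fit$draws[idx, "sigma_e"]
  ll <- matrix(0, length(idx), dat$n)
  for (s in seq_along(idx))
    ll[s, ] <- stats::dnorm(dat$y, mu[s, ], se[s], log = TRUE)
  ll
}

psis_loo <- function(ll) {
  n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    elpd_i[i] <- logsumexp(sm$lw + ll[, i])
    k_i[i] <- sm$k
  }
  list(elpd_i = elpd_i, elpd = sum(elpd_i),
       se = sqrt(n * stats::var(elpd_i)), k = k_i)
}

#' Compare fitted models by approximate leave-one-out cross-validation
#'
#' Estimates each model's expected log pointwise predictive density (elpd)
#' by Pareto-smoothed importance sampling over the posterior draws, using
#' the conditional pointwise likelihood (random effects drawn from their
#' conditional posterior). Models must be fitted to the same data; the
#' table is ranked by elpd, with pairwise differences against the best
#' model and their standard errors.
#'
#' @param fits Named list of `fit_result` objects on identical data.
#' @param max_draws Posterior draws used per model.
#' @return A data frame ranked by `elpd`: columns `model`, `elpd`, `se`,
#'   `elpd_diff`, `se_diff`, `bad_k` (count of Pareto k > 0.7). A warning
#'   is raised if more than 20% of observations have high Pareto k.
#' @export
compare_models <- function(fits, max_draws = 400) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$model_id, "")
  ys <- lapply(fits, function(f) f$data$y)
  if (!all(vapply(ys, function(y) isTRUE(all.equal(y, ys[[1]])), TRUE)))
    stop("fits must be on identical data")
  loos <- lapply(fits, function(f) psis_loo(pointwise_loglik(f, max_draws)))
  bad <- vapply(loos, function(l) sum(l$k > 0.7), 0L)
  n <- length(loos[[1]]$elpd_i)
  if (any(bad / n > 0.2))
    warning("more than 20% of observations have Pareto k > 0.7; ",
            "elpd estimates may be unreliable")
  elpd <- vapply(loos, `[[`, 0, "elpd")
  best <- which.max(elpd)
  diff <- elpd - elpd[best]
  se_diff <- vapply(seq_along(loos), function(i) {
    d <- loos[[i]]$elpd_i - loos[[best]]$elpd_i
    sqrt(n * stats::var(d))
  }, 0)
  out <- data.frame(model = names(fits), elpd = elpd,
                    se = vapply(loos, `[[`, 0, "se"),
                    elpd_diff = diff, se_diff = se_diff,
                    bad_k = bad, row.names = NULL)
  out[order(-out$elpd), ]
}
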