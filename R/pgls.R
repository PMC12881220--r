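#' Specify a Bayesian allometric model
#'
#' Three nested models estimate the allometric intercept C and slope b of
#' log(corrected rate) on log(mass) at genus level:
#' \describe{
#'   \item{M1}{plain Bayesian linear regression (no grouping structure);}
#'   \item{M2}{adds nested Order/Family random intercepts;}
#'   \item{M3}{adds an Order random intercept plus a phylogenetic effect
#'     with covariance sigma_p^2 * V(lambda), where V is the Grafen
#'     variance-covariance matrix and lambda is Pagel's lambda.}
#' }
#' Random effects are marginalised analytically (GLS likelihood); the MCMC
#' samples the variance components and lambda, with (C, b) drawn from their
#' exact conditional normal per retained iteration.
#'
#' Priors are weakly informative: Normal(0, 10^2) on C and b on the working
#' log scale, half-Normal(0, 5) on all standard deviations, Uniform(0, 1)
#' on lambda.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`.
#' @param chains Number of MCMC chains (default 4).
#' @param iter_warmup,iter_sampling Iterations per chain (defaults 1500 and 2500).
#' @param seed Integer seed.
#' @param prior_beta_sd,prior_sd_scale Prior scales for (C, b) and the SDs.
#' @return A `model_spec` list.
#' @export
model_spec <- function(model_id = c("M3", "M1", "M2"),
                       chains = 4, iter_warmup = 1500, iter_sampling = 2500,
                       seed = 1, prior_beta_sd = 10, prior_sd_scale = 5) {
  model_id <- match.arg(model_id)
  structure(list(model_id = model_id, chains = chains,
                 iter_warmup = iter_warmup, iter_sampling = iter_sampling,
                 seed = as.integer(seed), prior_beta_sd = prior_beta_sd,
                 prior_sd_scale = prior_sd_scale),
            class = "model_spec")
}

# ---- internal likelihood machinery ----------------------------------------

indicator_matrix <- function(labels) {
  lev <- sort(unique(labels))
  Z <- matrix(0, length(labels), length(lev),
              dimnames = list(NULL, lev))
  Z[cbind(seq_along(labels), match(labels, lev))] <- 1
  Z
}

# Build the fixed per-fit data structures. For M3 the covariance is
# eigen-decomposed once: sigma_p^2 V(lambda) + sigma_e^2 I is diagonal in
# the eigenbasis of V, and the Order random effect is handled by Woodbury.
build_fit_data <- function(model_id, genus_table, V = NULL) {
  y <- genus_table$log_rate_corrected
  m <- genus_table$log_mass
  n <- length(y)
  if (n < 3) stop("need at least 3 genera to fit")
  X <- cbind(intercept = rep(1, n), log_mass = m)

  orders <- as.character(genus_table$order)
  if (length(orders) == 0 || all(is.na(orders)))
    orders <- rep("order_1", n)
  orders[is.na(orders)] <- "order_unknown"
  Zo <- indicator_matrix(orders)

  dat <- list(model_id = model_id, y = y, X = X, n = n,
              genus = genus_table$genus, order = orders)

  if (model_id == "M1") {
    dat$U <- matrix(0, n, 0); dat$ngroup <- integer(0)
    dat$Q <- NULL; dat$ev <- rep(1, n)
    dat$yr <- y; dat$Xr <- X; dat$Ur <- dat$U
  } else if (model_id == "M2") {
    fams <- as.character(genus_table$family)
    if (length(fams) == 0 || all(is.na(fams))) fams <- orders
    fams[is.na(fams)] <- "family_unknown"
    Zf <- indicator_matrix(paste(orders, fams, sep = "/"))
    dat$U <- cbind(Zo, Zf)
    dat$ngroup <- c(order = ncol(Zo), family = ncol(Zf))
    dat$Q <- NULL; dat$ev <- rep(1, n)
    dat$yr <- y; dat$Xr <- X; dat$Ur <- dat$U
  } else { # M3
    if (is.null(V)) stop("M3 requires a phylogenetic covariance matrix")
    if (!all(genus_table$genus %in% rownames(V)))
      stop("covariance matrix does not cover all genera in the table")
    V <- V[genus_table$genus, genus_table$genus]
    ed <- eigen((V + t(V)) / 2, symmetric = TRUE)
    dat$Q <- ed$vectors
    dat$ev <- pmax(ed$values, 0)
    dat$U <- Zo
    dat$ngroup <- c(order = ncol(Zo))
    dat$yr <- drop(crossprod(dat$Q, y))
    dat$Xr <- crossprod(dat$Q, X)
    dat$Ur <- crossprod(dat$Q, Zo)
    dat$V <- V
    dat$LV <- tryCatch(chol(V + diag(1e-10, n)), error = function(e) NULL)
  }
  dat
}

# Unpack the sampled parameter vector (on the unconstrained scale) into
# natural-scale variance components. Parameter layout:
#  M1: log sigma_e
#  M2: log sigma_e, log sigma_o, log sigma_f
#  M3: log sigma_e, log sigma_o, log sigma_p, logit lambda
unpack_theta <- function(phi, model_id) {
  if (model_id == "M1") {
    list(sigma_e = exp(phi[1]))
  } else if (model_id == "M2") {
    list(sigma_e = exp(phi[1]), sigma_o = exp(phi[2]), sigma_f = exp(phi[3]))
  } else {
    list(sigma_e = exp(phi[1]), sigma_o = exp(phi[2]),
         sigma_p = exp(phi[3]), lambda = stats::plogis(phi[4]))
  }
}

# Diagonal of the rotated dense covariance part and the random-effect
# variance vector for the Woodbury correction.
theta_cov_parts <- function(th, dat) {
  if (dat$model_id == "M1") {
    d <- rep(th$sigma_e^2, dat$n); su2 <- numeric(0)
  } else if (dat$model_id == "M2") {
    d <- rep(th$sigma_e^2, dat$n)
    su2 <- c(rep(th$sigma_o^2, dat$ngroup["order"]),
             rep(th$sigma_f^2, dat$ngroup["family"]))
  } else {
    d <- th$sigma_p^2 * th$lambda * dat$ev +
      th$sigma_p^2 * (1 - th$lambda) + th$sigma_e^2
    su2 <- rep(th$sigma_o^2, dat$ngroup["order"])
  }
  list(d = pmax(d, 1e-12), su2 = su2)
}

# Log marginal likelihood with (C, b) integrated out under their normal
# prior: y ~ N(0, D + W diag(sw2) W') with W = [U, X].
log_marg_lik <- function(phi, dat, prior_beta_sd) {
  th <- unpack_theta(phi, dat$model_id)
  cp <- theta_cov_parts(th, dat)
  W <- cbind(dat$Ur, dat$Xr)
  sw2 <- c(cp$su2, rep(prior_beta_sd^2, ncol(dat$Xr)))
  d <- cp$d
  Wd <- W / d
  A <- crossprod(W, Wd) + diag(1 / sw2, length(sw2))
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(-Inf)
  Wy <- drop(crossprod(Wd, dat$yr))
  quad <- sum(dat$yr^2 / d) - sum(backsolve(cA, Wy, transpose = TRUE)^2)
  logdet <- sum(log(d)) + 2 * sum(log(diag(cA))) + sum(log(sw2))
  -0.5 * (dat$n * log(2 * pi) + logdet + quad)
}

log_prior <- function(phi, dat, sd_scale) {
  th <- unpack_theta(phi, dat$model_id)
  lp <- 0
  for (nm in intersect(names(th), c("sigma_e", "sigma_o", "sigma_f",
                                    "sigma_p"))) {
    s <- th[[nm]]
    lp <- lp - s^2 / (2 * sd_scale^2) + log(s)  # half-normal + log-Jacobian
  }
  if (!is.null(th$lambda)) {
    la <- th$lambda
    if (la <= 0 || la >= 1) return(-Inf)
    lp <- lp + log(la) + log1p(-la)             # uniform + logit Jacobian
  }
  lp
}

# Apply Sigma^{-1} (random effects only, no beta prior) to a matrix of
# columns, using the Woodbury identity in the rotated basis.
sigma_solve <- function(M, d, Ur, su2) {
  Md <- M / d
  if (length(su2) == 0) return(Md)
  Ud <- Ur / d
  A <- crossprod(Ur, Ud) + diag(1 / su2, length(su2))
  Md - Ud %*% solve(A, crossprod(Ud, M))
}

# Exact conditional draw of beta = (C, b) given variance components.
draw_beta <- function(dat, th, prior_beta_sd) {
  cp <- theta_cov_parts(th, dat)
  SiX <- sigma_solve(dat$Xr, cp$d, dat$Ur, cp$su2)
  A <- crossprod(dat$Xr, SiX) + diag(1 / prior_beta_sd^2, 2)
  mu <- solve(A, crossprod(SiX, dat$yr))
  L <- chol(solve(A))
  drop(mu + t(L) %*% stats::rnorm(2))
}

split_rhat <- function(draws_by_chain) {
  # draws_by_chain: list of numeric vectors (one per chain), equal length
  halves <- unlist(lapply(draws_by_chain, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); nh <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- nh * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((nh - 1) / nh * Wv + B / nh) / Wv)
}

# ---- the fitting routine ---------------------------------------------------

#' Fit an allometric intercept model by MCMC
#'
#' Runs adaptive random-walk Metropolis over the variance components (and
#' Pagel's lambda for M3) of the marginal GLS likelihood, with the fixed
#' effects (C, b) integrated out analytically during sampling and drawn
#' from their exact conditional normal for each retained iteration.
#' Split-R-hat convergence diagnostics are attached; a fit with max
#' R-hat > 1.05 is flagged non-converged and downstream operations refuse
#' it unless forced.
#'
#' @param spec A [model_spec()].
#' @param genus_table Genus-mean table (see [genus_means()]) for a single
#'   rate kind and metabolic group, with columns `genus`, `order`,
#'   (`family`,) `log_rate_corrected`, `log_mass`.
#' @param covariance Phylogenetic covariance matrix from [phylo_vcv()]
#'   (required for M3, ignored otherwise). Diagonal must be 1 (Grafen
#'   scaling).
#' @return A `fit_result` with elements `draws` (matrix of posterior draws),
#'   `summary` (median, 95% CRI, R-hat per parameter), `converged`, and the
#'   internal data needed by downstream operations.
#' @export
fit_allometry <- function(spec, genus_table, covariance = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- build_fit_data(spec$model_id, genus_table, covariance)
  k <- switch(spec$model_id, M1 = 1, M2 = 3, M3 = 4)
  par_names <- switch(spec$model_id,
    M1 = "sigma_e",
    M2 = c("sigma_e", "sigma_o", "sigma_f"),
    M3 = c("sigma_e", "sigma_o", "sigma_p", "lambda"))

  set.seed(spec$seed)
  # crude starting values from OLS residual spread
  ols <- stats::lm.fit(dat$X, dat$y)
  s0 <- log(max(stats::sd(ols$residuals), 1e-2))

  run_chain <- function(chain_id) {
    set.seed(spec$seed + 1000L * chain_id)
    phi <- switch(spec$model_id,
      M1 = s0 + stats::rnorm(1, 0, 0.2),
      M2 = c(s0, s0 - 0.5, s0 - 0.5) + stats::rnorm(3, 0, 0.2),
      M3 = c(c(s0, s0 - 0.5, s0) + stats::rnorm(3, 0, 0.2),
             stats::rnorm(1, 0, 0.5)))
    lp <- log_marg_lik(phi, dat, spec$prior_beta_sd) +
      log_prior(phi, dat, spec$prior_sd_scale)
    n_w <- spec$iter_warmup; n_s <- spec$iter_sampling
    scale <- 0.3
    hist_w <- matrix(NA_real_, n_w, k)
    prop_chol <- diag(0.25, k)
    keep_phi <- matrix(NA_real_, n_s, k)
    acc <- 0
    for (it in seq_len(n_w + n_s)) {
      step <- drop(t(prop_chol) %*% stats::rnorm(k)) * scale
      cand <- phi + step
      lp_c <- log_marg_lik(cand, dat, spec$prior_beta_sd) +
        log_prior(cand, dat, spec$prior_sd_scale)
      if (is.finite(lp_c) && log(stats::runif(1)) < lp_c - lp) {
        phi <- cand; lp <- lp_c; acc <- acc + 1
      }
      if (spec$model_id == "M3") {
        # slide along the likelihood-invariant direction: only
        # s = sigma_p^2 lambda and c = sigma_p^2 (1 - lambda) + sigma_e^2
        # enter the marginal likelihood, so this move needs no
        # likelihood evaluation (prior ratio + Jacobian only)
        se2 <- exp(2 * phi[1]); sp2 <- exp(2 * phi[3])
        la <- stats::plogis(phi[4])
        s_inv <- sp2 * la; c_inv <- se2 + sp2 * (1 - la)
        la2 <- stats::plogis(phi[4] + stats::rnorm(1))
        sp2_2 <- s_inv / la2
        se2_2 <- c_inv - sp2_2 * (1 - la2)
        if (se2_2 > 0) {
          cand2 <- c(log(se2_2) / 2, phi[2], log(sp2_2) / 2,
                     stats::qlogis(la2))
          dlp <- log_prior(cand2, dat, spec$prior_sd_scale) -
            log_prior(phi, dat, spec$prior_sd_scale) +
            log(se2) - log(se2_2)
          if (is.finite(dlp) && log(stats::runif(1)) < dlp) {
            lp <- lp + log_prior(cand2, dat, spec$prior_sd_scale) -
              log_prior(phi, dat, spec$prior_sd_scale)
            phi <- cand2
          }
        }
      }
      if (it <= n_w) {
        hist_w[it, ] <- phi
        # Robbins-Monro on the global scale toward ~30% acceptance
        rate <- acc / it
        scale <- scale * exp((rate - 0.3) / sqrt(it))
        # staged covariance adaptation from the accumulating history
        if (it %in% floor(n_w * c(0.3, 0.6, 0.9)) && it >= 50) {
          lo <- max(1, floor(it / 2))
          S <- stats::cov(hist_w[lo:it, , drop = FALSE]) + diag(1e-8, k)
          prop_chol <- tryCatch(chol(2.38^2 / k * S),
                                error = function(e) prop_chol)
          scale <- 1
        }
      } else {
        keep_phi[it - n_w, ] <- phi
      }
    }
    keep_phi
  }

  chains <- lapply(seq_len(spec$chains), run_chain)

  # conditional (C, b) draw for every retained iteration
  draws_list <- lapply(seq_along(chains), function(ci) {
    ph <- chains[[ci]]
    set.seed(spec$seed + 7000L + ci)
    betas <- t(apply(ph, 1, function(p) {
      draw_beta(dat, unpack_theta(p, dat$model_id), spec$prior_beta_sd)
    }))
    nat <- t(apply(ph, 1, function(p) {
      unlist(unpack_theta(p, dat$model_id))
    }))
    if (k == 1) nat <- t(nat)
    colnames(nat) <- par_names
    cbind(C = betas[, 1], b = betas[, 2], nat)
  })
  draws <- do.call(rbind, draws_list)

  rhat <- vapply(colnames(draws), function(cn) {
    split_rhat(lapply(draws_list, function(d) d[, cn]))
  }, 0)

  qs <- t(apply(draws, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  summary <- data.frame(parameter = colnames(draws),
                        median = qs[, 1], cri_lo = qs[, 2], cri_hi = qs[, 3],
                        sd = apply(draws, 2, stats::sd),
                        rhat = rhat, row.names = NULL)

  fit <- structure(list(
    spec = spec, draws = draws, draws_by_chain = draws_list,
    summary = summary, rhat = rhat,
    converged = all(is.finite(rhat)) && max(rhat) <= 1.05,
    data = dat), class = "fit_result")
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Bayesian allometric fit (", x$spec$model_id, "), n = ",
      x$data$n, " genera\n", sep = "")
  s <- x$summary
  s[, 2:6] <- round(s[, 2:6], 4)
  print(s, row.names = FALSE)
  cat(if (x$converged) "converged (max split-R-hat <= 1.05)\n" else
        "WARNING: not converged\n")
  invisible(x)
}

check_converged <- function(fit, force = FALSE) {
  if (!fit$converged && !force)
    stop("fit has not converged (max R-hat > 1.05); pass force = TRUE ",
         "to override")
  invisible(TRUE)
}

#' Fraction of the intercept posterior relative to a reference value
#'
#' @param fit A converged `fit_result`.
#' @param reference Reference intercept value on the fit's log scale.
#' @param side `"below"` or `"above"`.
#' @param parameter Which parameter's posterior to use (default `"C"`).
#' @param force Proceed despite a non-converged fit.
#' @return Proportion of posterior draws strictly below/above `reference`.
#' @export
posterior_fraction_relative <- function(fit, reference,
                                        side = c("below", "above"),
                                        parameter = "C", force = FALSE) {
  side <- match.arg(side)
  check_converged(fit, force)
  x <- fit$draws[, parameter]
  if (side == "below") mean(x < reference) else mean(x > reference)
}

# ---- conditional random-effect draws (shared by genus_intercept / LOO) ----

# For each retained posterior draw, draw the Order effects and (M3) the
# phylogenetic effects from their exact conditional given y, using
# Matheron's rule: u | y ~ u0 + G T' Sigma^{-1} (y - X beta - T u0 - e0)
# with (u0, e0) prior draws, avoiding a per-draw Cholesky of the
# conditional covariance.
draw_random_effects <- function(fit, max_draws = 400) {
  dat <- fit$data
  if (dat$model_id == "M1")
    return(list(idx = seq_len(min(max_draws, nrow(fit$draws))),
                fitted_re = matrix(0, min(max_draws, nrow(fit$draws)),
                                   dat$n)))
  S <- nrow(fit$draws)
  idx <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else
    seq_len(S)
  n <- dat$n
  re <- matrix(0, length(idx), n)
  ord_eff <- matrix(0, length(idx), ncol(dat$U[, seq_len(dat$ngroup[1]),
                                               drop = FALSE]))
  set.seed(fit$spec$seed + 31L)
  for (s in seq_along(idx)) {
    dr <- fit$draws[idx[s], ]
    th <- as.list(dr[-(1:2)])
    beta <- dr[1:2]
    cp <- theta_cov_parts(th, dat)
    r <- dat$yr - drop(dat$Xr %*% beta)
    if (dat$model_id == "M2") {
      qo <- dat$ngroup["order"]; qf <- dat$ngroup["family"]
      G <- c(rep(th$sigma_o^2, qo), rep(th$sigma_f^2, qf))
      u0 <- stats::rnorm(length(G), 0, sqrt(G))
      e0 <- stats::rnorm(n, 0, th$sigma_e)
      y0 <- drop(dat$Ur %*% u0) + e0
      w <- sigma_solve(cbind(r - y0), cp$d, dat$Ur, cp$su2)
      u <- u0 + G * drop(crossprod(dat$Ur, w))
      re[s, ] <- drop(dat$U %*% u)
      ord_eff[s, ] <- u[seq_len(qo)]
    } else { # M3 (rotated basis)
      qo <- dat$ngroup["order"]
      u0 <- stats::rnorm(qo, 0, th$sigma_o)
      if (is.null(dat$LV)) stop("covariance Cholesky unavailable")
      p0 <- sqrt(th$lambda) * th$sigma_p *
        drop(t(dat$LV) %*% stats::rnorm(n)) +
        sqrt(1 - th$lambda) * th$sigma_p * stats::rnorm(n)
      e0 <- stats::rnorm(n, 0, th$sigma_e)
      p0r <- drop(crossprod(dat$Q, p0))
      y0 <- drop(dat$Ur %*% u0) + p0r + crossprod(dat$Q, e0)
      w <- sigma_solve(cbind(r - y0), cp$d, dat$Ur, cp$su2)
      u <- u0 + th$sigma_o^2 * drop(crossprod(dat$Ur, w))
      # phylo conditional: p0 + sigma_p^2 V(lambda) Sigma^{-1} resid
      dphy <- th$sigma_p^2 * th$lambda * dat$ev + th$sigma_p^2 *
        (1 - th$lambda)
      p <- p0r + dphy * drop(w)
      re[s, ] <- drop(dat$Q %*% p) + drop(dat$U %*% u)
      ord_eff[s, ] <- u
    }
  }
  list(idx = idx, fitted_re = re, order_eff = ord_eff)
}

#' Posterior distribution of a genus-level intercept
#'
#' The genus-level intercept is the group intercept C plus the genus's
#' Order random effect plus (M3) its phylogenetic effect, summed per
#' posterior draw and summarised as the median with a central 95% credible
#' interval.
#'
#' @param fit A converged M2 or M3 `fit_result`.
#' @param genus Genus name(s) present in the fitted table.
#' @param max_draws Number of (thinned) posterior draws to use.
#' @param force Proceed despite a non-converged fit.
#' @return A data frame with one row per genus: `median`, `cri_lo`,
#'   `cri_hi`; the per-draw matrix is attached as attribute `"draws"`.
#' @export
genus_intercept <- function(fit, genus, max_draws = 400, force = FALSE) {
  check_converged(fit, force)
  if (fit$data$model_id == "M1")
    stop("genus-level intercepts require a model with random effects")
  missing_g <- setdiff(genus, fit$data$genus)
  if (length(missing_g))
    stop("unknown genus: ", paste(missing_g, collapse = ", "))
  re <- draw_random_effects(fit, max_draws)
  pos <- match(genus, fit$data$genus)
  dr <- fit$draws[re$idx, "C"] + re$fitted_re[, pos, drop = FALSE]
  # the fitted random effect contains the slope-independent deviations only
  qs <- t(apply(dr, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  out <- data.frame(genus = genus, median = qs[, 1], cri_lo = qs[, 2],
                    cri_hi = qs[, 3], row.names = NULL)
  attr(out, "draws") <- dr
  out
}

#' Frequentist per-group ANCOVA intercepts
#'
#' Ordinary least squares with group-specific intercepts and slopes,
#' fitted as a separate regression per metabolic group (equivalently a
#' fully interacted joint model), matching the legacy estimation approach.
#'
#' @param table Data frame with columns `metabolic_group`, `log_mass`,
#'   `log_rate_corrected`.
#' @return Data frame: one row per group with `intercept`, `slope`,
#'   `ci_lo`, `ci_hi` (95% t-interval on the intercept), `n`.
#' @export
ancova_frequentist <- function(table) {
  stopifnot(all(c("metabolic_group", "log_mass", "log_rate_corrected")
                %in% names(table)))
  groups <- unique(table$metabolic_group)
  rows <- lapply(groups, function(g) {
    d <- table[table$metabolic_group == g, ]
    if (nrow(d) < 3) stop("group '", g, "' has fewer than 3 points")
    f <- stats::lm(log_rate_corrected ~ log_mass, data = d)
    ci <- stats::confint(f, "(Intercept)", level = 0.95)
    data.frame(metabolic_group = g,
               intercept = unname(stats::coef(f)[1]),
               slope = unname(stats::coef(f)[2]),
               ci_lo = ci[1], ci_hi = ci[2], n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
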