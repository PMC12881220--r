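test_that("M1 recovers known regression parameters", {
  gt <- make_genus_table(n = 200, C = 5, b = 0.75, sigma = 0.3, seed = 42)
  f <- fit_allometry(model_spec("M1", seed = 7), gt)
  expect_true(f$converged)
  s <- f$summary
  expect_equal(s$median[s$parameter == "C"], 5, tolerance = 0.1 / 5)
  expect_equal(s$median[s$parameter == "b"], 0.75, tolerance = 0.02 / 0.75)
  expect_equal(s$median[s$parameter == "sigma_e"], 0.3, tolerance = 0.15)
  # CRI bounds are ordered
  expect_true(all(s$cri_lo <= s$median & s$median <= s$cri_hi))
})

test_that("M3 on lambda = 0 data concentrates lambda near 0 and matches M1", {
  d <- make_phylo_dataset(n = 100, C = 4, lambda = 0, sigma_p = 0.3,
                          sigma_o = 0, sigma_e = 0.4, seed = 21)
  f1 <- fit_allometry(model_spec("M1", seed = 3), d$genus_table)
  f3 <- fit_allometry(model_spec("M3", seed = 3), d$genus_table, d$V)
  la <- f3$summary$median[f3$summary$parameter == "lambda"]
  expect_lt(la, 0.5)
  C1 <- f1$summary$median[f1$summary$parameter == "C"]
  C3 <- f3$summary$median[f3$summary$parameter == "C"]
  sd3 <- f3$summary$sd[f3$summary$parameter == "C"]
  expect_lt(abs(C1 - C3), 3 * sd3)
})

test_that("posterior fractions behave like the empirical CDF", {
  gt <- make_genus_table(n = 80, seed = 5)
  f <- fit_allometry(model_spec("M1", seed = 2), gt)
  med <- f$summary$median[f$summary$parameter == "C"]
  expect_equal(posterior_fraction_relative(f, med, "below"), 0.5,
               tolerance = 0.02)
  expect_equal(posterior_fraction_relative(f, -1e6, "below"), 0)
  expect_equal(posterior_fraction_relative(f, -1e6, "above"), 1)
  # reference 2 posterior SDs above the mean: fraction below ~ 0.977
  mu <- mean(f$draws[, "C"]); sd_c <- sd(f$draws[, "C"])
  expect_equal(posterior_fraction_relative(f, mu + 2 * sd_c, "below"),
               0.977, tolerance = 0.02)
})

test_that("genus intercepts recover an engineered genus offset", {
  set.seed(8)
  d <- make_phylo_dataset(n = 80, C = 3, lambda = 0.6, sigma_p = 0.6,
                          sigma_o = 0.3, sigma_e = 0.2, seed = 31)
  gt <- d$genus_table
  target <- gt$genus[10]
  gt$log_rate_corrected[10] <- gt$log_rate_corrected[10] + 2
  f <- fit_allometry(model_spec("M3", seed = 5), gt, d$V)
  gi <- genus_intercept(f, c(target, gt$genus[40]), force = TRUE)
  Cmed <- f$summary$median[f$summary$parameter == "C"]
  # the offset genus sits well above the group-level intercept
  expect_gt(gi$median[1] - Cmed, 0.8)
  expect_error(genus_intercept(f, "not_a_genus", force = TRUE), "unknown")
})

test_that("group-level genus-intercept spread covers the simulated spread", {
  d <- make_phylo_dataset(n = 100, C = 5, lambda = 0.8, sigma_p = 1,
                          sigma_o = 0.4, sigma_e = 0.2, seed = 77)
  f <- fit_allometry(model_spec("M3", seed = 9), d$genus_table, d$V)
  gi <- genus_intercept(f, d$genus_table$genus, force = TRUE)
  true_dev <- d$sim$truth$order_eff + d$sim$truth$phylo_eff
  true_spread <- diff(range(true_dev[match(d$genus_table$genus,
                                           d$sim$truth$genus)]))
  est_spread <- max(gi$cri_hi) - min(gi$cri_lo)
  expect_gte(est_spread, true_spread * 0.8)
})

test_that("frequentist ANCOVA matches closed-form least squares", {
  # perfectly collinear toy data: exact intercept, zero-width CI
  m <- seq(-3, 3, by = 0.5)
  toy <- data.frame(metabolic_group = "ecto_invertebrate",
                    log_mass = m, log_rate_corrected = 2 + 0.75 * m)
  a <- suppressWarnings(ancova_frequentist(toy))  # exact fit by design
  expect_equal(a$intercept, 2)
  expect_equal(a$slope, 0.75)
  expect_lt(a$ci_hi - a$ci_lo, 1e-8)

  # normal-equations oracle on noisy data
  set.seed(14)
  d <- data.frame(metabolic_group = "ecto_vertebrate",
                  log_mass = rnorm(50),
                  log_rate_corrected = 1 + 0.6 * rnorm(50) + rnorm(50))
  a2 <- ancova_frequentist(d)
  Xm <- cbind(1, d$log_mass)
  beta_hat <- solve(t(Xm) %*% Xm, t(Xm) %*% d$log_rate_corrected)
  expect_equal(a2$intercept, beta_hat[1], tolerance = 1e-10)
  expect_equal(a2$slope, beta_hat[2], tolerance = 1e-10)

  # two groups fitted separately equal the per-group joint fit
  d2 <- rbind(transform(d, metabolic_group = "g1"),
              transform(d, log_rate_corrected = 3 - 0.2 * log_mass +
                          rnorm(50, 0, 0.1), metabolic_group = "g2"))
  a3 <- ancova_frequentist(d2)
  for (g in c("g1", "g2")) {
    sub <- d2[d2$metabolic_group == g, ]
    ref <- lm(log_rate_corrected ~ log_mass, sub)
    expect_equal(a3$intercept[a3$metabolic_group == g],
                 unname(coef(ref)[1]))
    expect_equal(a3$slope[a3$metabolic_group == g], unname(coef(ref)[2]))
  }
  expect_error(ancova_frequentist(toy[1:2, ]), "fewer than 3")
})

test_that("intercept CRI coverage is calibrated over replicates", {
  # quick M1 calibration check (the slower phylogenetic version runs in
  # the acceptance suite)
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    gt <- make_genus_table(n = 50, C = 4, b = 0.75, sigma = 0.4,
                           seed = 100 + r)
    f <- fit_allometry(model_spec("M1", chains = 2, iter_warmup = 400,
                                  iter_sampling = 600, seed = r), gt)
    s <- f$summary
    if (s$cri_lo[1] <= 4 && 4 <= s$cri_hi[1]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
})
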