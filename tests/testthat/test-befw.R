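test_that("a lone producer converges to its carrying capacity", {
  web <- one_producer_web()
  pars <- befw_params(web, updated_coefficients())
  res <- simulate_befw(web, pars, B_init = 0.1, t_max = 500)
  expect_equal(res$biomass[nrow(res$biomass), 1], pars$K,
               tolerance = 1e-4)
  # with zero metabolism and no feeding, producer biomass is monotone
  # non-decreasing toward K
  expect_true(all(diff(res$biomass[, 1]) >= -1e-6))
})

test_that("a consumer without prey declines exponentially to extinction", {
  A <- matrix(0L, 2, 2); A[2, 1] <- 0L  # consumer 2 has no prey
  # species 2 is a consumer (positive x) with nothing to eat
  web <- two_species_web()
  web$adjacency[2, 1] <- 0L
  pars <- befw_params(web, updated_coefficients())
  pars$x[2] <- 0.5
  res <- simulate_befw(web, pars, B_init = c(0.5, 0.5), t_max = 100)
  expect_true(res$extinct[2])
  expect_equal(res$biomass[nrow(res$biomass), 2], 0)
  # decay matches exp(-x t) before the extinction cut
  t5 <- res$time[6]
  expect_equal(res$biomass[6, 2], 0.5 * exp(-0.5 * t5), tolerance = 1e-3)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  web <- two_species_web()
  pars <- befw_params(web, updated_coefficients())
  B0 <- c(0.4, 0.2)
  res <- simulate_befw(web, pars, B_init = B0, t_max = 50, n_save = 100)
  ora <- rk4_oracle(web, pars, B0, 50, dt = 0.005)
  idx <- match(round(res$time, 8), round(ora$time, 8))
  expect_true(all(is.finite(idx)))
  expect_lt(max(abs(res$biomass - ora$biomass[idx, ])), 1e-3)
})

test_that("dynamics preserve non-negativity and determinism", {
  web <- generate_niche_web(30, 0.15, seed = 11, Z = 10)
  pars <- befw_params(web, legacy_coefficients())
  r1 <- simulate_befw(web, pars, seed = 3)
  r2 <- simulate_befw(web, pars, seed = 3)
  expect_identical(r1$biomass, r2$biomass)
  expect_true(all(r1$biomass >= 0))
  m1 <- befw_metrics(r1); m2 <- befw_metrics(r2)
  expect_identical(m1, m2)
})

test_that("metrics match closed forms on constructed trajectories", {
  # sinusoidal trajectory with known CV
  tt <- seq(0, 2 * pi * 10, length.out = 201)
  B <- 2 + 0.5 * sin(tt)
  fake <- structure(list(
    time = tt, biomass = cbind(B, B), extinct = c(FALSE, FALSE), S = 2,
    extinction_threshold = 1e-6), class = "befw_result")
  m <- befw_metrics(fake, last_n_biomass = 201, last_n_community = 201)
  cv_expected <- sd(B) / mean(B)
  expect_equal(m$population_stability, -cv_expected, tolerance = 1e-6)
  expect_equal(m$community_stability, -log(cv_expected), tolerance = 1e-6)
  expect_equal(m$persistence, 1)
  expect_equal(m$total_biomass, 2 * mean(B))

  # constant trajectories: CV 0, community stability capped finite
  const <- structure(list(
    time = tt, biomass = cbind(rep(1, 201), rep(2, 201)),
    extinct = c(FALSE, FALSE), S = 2,
    extinction_threshold = 1e-6), class = "befw_result")
  mc <- befw_metrics(const, last_n_biomass = 100, last_n_community = 50)
  expect_equal(mc$population_stability, 0)
  expect_true(is.finite(mc$community_stability))
  expect_gt(mc$community_stability, 30)

  # all-extinct community
  dead <- structure(list(
    time = tt, biomass = matrix(0, 201, 2), extinct = c(TRUE, TRUE),
    S = 2, extinction_threshold = 1e-6), class = "befw_result")
  md <- befw_metrics(dead)
  expect_equal(md$persistence, 0)
  expect_equal(md$total_biomass, 0)
  expect_true(is.na(md$population_stability))
})
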