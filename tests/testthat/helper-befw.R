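# BEFW test helpers: an independent fixed-step RK4 oracle and tiny webs.

# Independent fixed-step RK4 integrator used as the dual-route oracle.
rk4_oracle <- function(web, params, B_init, t_max, dt) {
  times <- seq(0, t_max, by = dt)
  parms <- list(A = web$adjacency, r = params$r, x = params$x,
                e = params$e, y = params$y, B0 = params$B0, h = params$h,
                K = params$K, producer = params$producer,
                alive = rep(1, web$S))
  f <- function(B) allomcoef:::befw_deriv(0, B, parms)[[1]]
  B <- B_init
  out <- matrix(NA_real_, length(times), web$S)
  out[1, ] <- B
  for (i in seq_along(times)[-1]) {
    k1 <- f(B); k2 <- f(B + dt / 2 * k1); k3 <- f(B + dt / 2 * k2)
    k4 <- f(B + dt * k3)
    B <- pmax(B + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    out[i, ] <- B
  }
  list(time = times, biomass = out)
}

one_producer_web <- function() {
  structure(list(S = 1L, adjacency = matrix(0L, 1, 1), niche = 0.1,
                 target_C = 0.01, realized_C = 0, trophic_level = 1,
                 Z = 10, mass = 1, metabolic_group = "producer",
                 seed = 1L), class = "food_web")
}

two_species_web <- function() {
  A <- matrix(c(0L, 0L, 1L, 0L), 2, 2, byrow = TRUE)
  structure(list(S = 2L, adjacency = A, niche = c(0.1, 0.5),
                 target_C = 0.25, realized_C = 0.25,
                 trophic_level = c(1, 2), Z = 10, mass = c(1, 10),
                 metabolic_group = c("producer", "ecto_invertebrate"),
                 seed = 1L), class = "food_web")
}

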