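#' Build BEFW dynamical parameters from a web and a coefficient set
#'
#' Mass-specific biological rates follow rate = a * M^(b - 1): producer
#' growth r_i = a_r * M_i^(b-1) (a_r = 1 for producers by timescale
#' normalisation) and consumer metabolic loss x_i = a_x * M_i^(b-1), with
#' a_x taken from the coefficient set by metabolic group. Remaining
#' parameters are the package defaults of the standard bioenergetic model:
#' maximum consumption y = 8 (relative to metabolism), assimilation
#' efficiency 0.45 for herbivory and 0.85 for carnivory, Holling functional
#' response with half-saturation B0 = 0.5 and hill exponent h = 2, shared
#' producer carrying capacity K = 1, extinction threshold 1e-6.
#'
#' @param web A `food_web` with masses and metabolic groups assigned.
#' @param coeffs A `coefficient_set` (e.g. [updated_coefficients()] or
#'   [legacy_coefficients()]).
#' @param y,B0,h,K,e_herbivory,e_carnivory,extinction_threshold Model
#'   constants (defaults above).
#' @param producer_x Mass-specific metabolic coefficient applied to
#'   producers (default 0: only consumer metabolism is parameterised by the
#'   coefficient sets under study).
#' @return A `befw_params` list with per-species vectors `r`, `x`, `e`
#'   (assimilation efficiency by resource) and the scalar constants.
#' @export
befw_params <- function(web, coeffs, y = 8, B0 = 0.5, h = 2, K = 1,
                        e_herbivory = 0.45, e_carnivory = 0.85,
                        extinction_threshold = 1e-6, producer_x = 0) {
  stopifnot(inherits(web, "food_web"), inherits(coeffs, "coefficient_set"),
            !is.null(web$mass))
  grp <- web$metabolic_group
  M <- web$mass
  b <- coeffs$exponents
  producer <- grp == "producer"
  r <- ifelse(producer, M^(b[["producer"]] - 1), 0)
  ax <- vapply(grp, function(g) {
    if (g == "producer") return(producer_x)
    if (!g %in% names(coeffs$a_x))
      stop("coefficient set has no a_x for group '", g, "'")
    coeffs$a_x[[g]]
  }, 0)
  bx <- vapply(grp, function(g) b[[g]], 0)
  x <- ifelse(producer, producer_x * M^(bx - 1), ax * M^(bx - 1))
  e <- ifelse(producer, e_herbivory, e_carnivory)  # efficiency by resource
  structure(list(r = r, x = x, e = e, y = y, B0 = B0, h = h, K = K,
                 extinction_threshold = extinction_threshold,
                 producer = producer, label = coeffs$label),
            class = "befw_params")
}

# Vectorised right-hand side of the bioenergetic system. `alive` masks
# extinct species out of the dynamics.
befw_deriv <- function(t, B, parms) {
  with(parms, {
    B <- pmax(B, 0) * alive
    Bh <- B^h
    denom <- B0^h + drop(A %*% Bh)
    feed <- drop(A %*% Bh) / denom            # sum_j F_ij
    gain <- x * y * B * feed
    pressure <- drop(crossprod(A, x * y * B / denom))  # consumer pressure
    loss <- Bh * pressure / e
    G <- 1 - sum(B[producer]) / K
    dB <- (r * G * B) * producer - x * B + gain - loss
    list(dB * alive)
  })
}

#' Simulate bioenergetic biomass dynamics on a food web
#'
#' Integrates the standard bioenergetic system
#' dB_i/dt = r_i G B_i [producer] - x_i B_i
#'   + sum_j x_i y B_i F_ij - sum_k x_k y B_k F_ki / e_i,
#' with logistic producer growth G = 1 - sum(producers) / K sharing one
#' carrying capacity, and a multi-resource Holling response
#' F_ij = B_j^h / (B0^h + sum_prey B_l^h). Integration uses `deSolve`'s
#' adaptive `lsoda` on a uniform save grid; after every saved step species
#' whose biomass falls below the extinction threshold are set to zero and
#' removed from the dynamics (no resurrection).
#'
#' @param web A `food_web`.
#' @param params A `befw_params`.
#' @param B_init Initial biomasses; if `NULL`, drawn Uniform(0.05, 1) under
#'   `seed`.
#' @param t_max Integration horizon in model time units (default 500).
#' @param n_save Number of saved steps on the uniform grid (default 250).
#' @param seed Seed for the initial condition draw.
#' @return A `befw_result` with `time`, `biomass` (time x species matrix),
#'   `extinct` (logical), and the inputs needed by [befw_metrics()].
#' @export
simulate_befw <- function(web, params, B_init = NULL, t_max = 500,
                          n_save = 250, seed = 1) {
  stopifnot(inherits(web, "food_web"), inherits(params, "befw_params"))
  S <- web$S
  if (is.null(B_init)) {
    set.seed(as.integer(seed))
    B_init <- stats::runif(S, 0.05, 1)
  }
  stopifnot(length(B_init) == S, all(B_init > 0))
  times <- seq(0, t_max, length.out = n_save + 1)
  thr <- params$extinction_threshold
  parms <- list(A = web$adjacency, r = params$r, x = params$x,
                e = params$e, y = params$y, B0 = params$B0, h = params$h,
                K = params$K, producer = params$producer,
                alive = rep(1, S))
  out <- matrix(NA_real_, n_save + 1, S)
  out[1, ] <- B <- B_init
  for (i in seq_len(n_save)) {
    sol <- deSolve::ode(y = B, times = times[c(i, i + 1)],
                        func = befw_deriv, parms = parms, method = "lsoda",
                        rtol = 1e-6, atol = 1e-8)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure at t = ", times[i],
           " (istate = ", attr(sol, "istate")[1], ")")
    B <- pmax(sol[nrow(sol), -1], 0)
    dead <- B < thr
    B[dead] <- 0
    parms$alive[dead] <- 0
    out[i + 1, ] <- B
  }
  structure(list(time = times, biomass = out,
                 extinct = parms$alive == 0,
                 S = S, params = params, web = web,
                 extinction_threshold = thr), class = "befw_result")
}

#' Summary metrics of a BEFW simulation
#'
#' Computes the four response variables of the simulation experiment:
#' \describe{
#'   \item{persistence}{fraction of the initial species with final biomass
#'     above the extinction threshold;}
#'   \item{total_biomass}{mean over the last `last_n_biomass` saved steps of
#'     the summed biomass;}
#'   \item{population_stability}{mean over persisting species of minus the
#'     coefficient of variation of their biomass over the last
#'     `last_n_biomass` saved steps;}
#'   \item{community_stability}{minus the log of the mean CV over the last
#'     `last_n_community` saved steps (CV floored at machine precision so a
#'     perfectly constant community reports a large finite value).}
#' }
#' With all species extinct, persistence and biomass are 0 and the
#' stability metrics are `NA`.
#'
#' @param result A `befw_result`.
#' @param last_n_biomass,last_n_community Trailing window lengths (saved
#'   steps) for the biomass/population metrics and the community metric.
#' @return A named list with the four metrics.
#' @export
befw_metrics <- function(result, last_n_biomass = 100,
                         last_n_community = 50) {
  stopifnot(inherits(result, "befw_result"))
  Bm <- result$biomass
  nt <- nrow(Bm)
  if (nt < max(last_n_biomass, last_n_community))
    stop("trajectory shorter than the requested window")
  final <- Bm[nt, ]
  alive <- final > result$extinction_threshold
  persistence <- mean(alive)
  win_b <- Bm[(nt - last_n_biomass + 1):nt, , drop = FALSE]
  total_biomass <- mean(rowSums(win_b))
  if (!any(alive))
    return(list(persistence = 0, total_biomass = 0,
                population_stability = NA_real_,
                community_stability = NA_real_))
  cv <- function(x) {
    mu <- mean(x)
    if (mu <= 0) return(NA_real_)
    stats::sd(x) / mu
  }
  cv_b <- apply(win_b[, alive, drop = FALSE], 2, cv)
  population_stability <- -mean(cv_b, na.rm = TRUE)
  win_c <- Bm[(nt - last_n_community + 1):nt, , drop = FALSE]
  cv_c <- apply(win_c[, alive, drop = FALSE], 2, cv)
  mean_cv <- max(mean(cv_c, na.rm = TRUE), .Machine$double.eps)
  list(persistence = persistence, total_biomass = total_biomass,
       population_stability = population_stability,
       community_stability = -log(mean_cv))
}
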