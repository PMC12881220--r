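#' Generate a niche-model food web
#'
#' Classic niche-model draw: each species i gets a niche value
#' n_i ~ Uniform(0, 1), a feeding range r_i = n_i * x_i with
#' x_i ~ Beta(1, (1 - 2C) / (2C)) so the expected connectance is C, and a
#' range centre c_i ~ Uniform(r_i / 2, n_i); i eats j iff n_j falls inside
#' [c_i - r_i/2, c_i + r_i/2]. Webs that are disconnected, contain isolated
#' species, have no basal species, miss the target connectance by more than
#' 25% (relative), or whose trophic levels cannot be solved (pure cannibal
#' loops) are rejected and redrawn.
#'
#' @param S Species richness (>= 2).
#' @param C Target connectance L / S^2, in (0, 0.5).
#' @param seed Integer seed (drawing is fully reproducible).
#' @param Z Predator-prey mass ratio used by [assign_masses()] (stored; pass
#'   `NA` to defer mass assignment).
#' @param max_tries Rejection budget (default 10000).
#' @param connectance_tol Relative tolerance on realised connectance.
#' @return A `food_web` list: `S`, `adjacency` (consumer rows x resource
#'   columns), `niche`, `target_C`, `realized_C`, `trophic_level`, `Z`,
#'   `mass`, `metabolic_group`, `seed`.
#' @export
generate_niche_web <- function(S, C, seed = 1, Z = NA_real_,
                               max_tries = 10000, connectance_tol = 0.25) {
  stopifnot(S >= 2, C > 0, C < 0.5)
  set.seed(as.integer(seed))
  beta_par <- (1 - 2 * C) / (2 * C)
  for (try in seq_len(max_tries)) {
    n <- stats::runif(S)
    x <- stats::rbeta(S, 1, beta_par)
    r <- n * x
    centre <- stats::runif(S, r / 2, n)
    lo <- centre - r / 2
    hi <- centre + r / 2
    A <- outer(seq_len(S), seq_len(S),
               function(i, j) n[j] >= lo[i] & n[j] <= hi[i])
    mode(A) <- "integer"
    L <- sum(A)
    realized <- L / S^2
    basal <- rowSums(A) == 0
    if (!any(basal)) next
    isolated <- rowSums(A) + colSums(A) == 0
    if (any(isolated)) next
    if (abs(realized - C) / C > connectance_tol) next
    # weak connectivity of the undirected feeding graph
    und <- (A + t(A)) > 0
    comp <- connected_components(und)
    if (max(comp) > 1) next
    tl <- tryCatch(trophic_levels_from_adjacency(A),
                   error = function(e) NULL)
    if (is.null(tl)) next
    web <- structure(list(
      S = S, adjacency = A, niche = n, target_C = C,
      realized_C = realized, trophic_level = tl, Z = Z,
      mass = NULL,
      metabolic_group = ifelse(basal, "producer", "ecto_invertebrate"),
      seed = as.integer(seed), tries = try), class = "food_web")
    if (is.finite(Z)) web <- assign_masses(web, Z)
    return(web)
  }
  stop("rejection budget exhausted: no admissible web in ", max_tries,
       " draws")
}

# label weakly connected components of an undirected adjacency (logical)
connected_components <- function(und) {
  S <- nrow(und)
  comp <- rep(0L, S)
  cur <- 0L
  for (s in seq_len(S)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nb <- which(und[v, ] | und[, v])
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

trophic_levels_from_adjacency <- function(A) {
  S <- nrow(A)
  nprey <- rowSums(A)
  W <- A / pmax(nprey, 1)
  M <- diag(S) - W
  tl <- tryCatch(solve(M, rep(1, S)), error = function(e)
    stop("singular trophic-level system (no basal path)"))
  if (any(!is.finite(tl)) || any(tl < 1 - 1e-8))
    stop("invalid trophic levels")
  pmax(tl, 1)
}

#' Prey-averaged trophic levels
#'
#' Basal species have level 1; a consumer's level is 1 plus the mean level
#' of its prey (including cannibalistic self-links). Solved as the linear
#' system (I - W) TL = 1 with W the row-normalised adjacency.
#'
#' @param web A `food_web`.
#' @return Numeric vector of trophic levels (>= 1).
#' @export
trophic_levels <- function(web) {
  stopifnot(inherits(web, "food_web"))
  trophic_levels_from_adjacency(web$adjacency)
}

#' Assign body masses from trophic levels
#'
#' Masses follow M_i = Z^(TL_i - 1): basal species have mass 1 and each
#' trophic step multiplies mass by the predator-prey mass ratio Z.
#'
#' @param web A `food_web`.
#' @param Z Predator-prey mass ratio (> 0).
#' @return The web with `mass` and `Z` filled in.
#' @export
assign_masses <- function(web, Z) {
  stopifnot(inherits(web, "food_web"), is.numeric(Z), Z > 0)
  web$Z <- Z
  web$mass <- Z^(web$trophic_level - 1)
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat("niche-model food web: S =", x$S,
      ", C target =", x$target_C,
      ", realized =", round(x$realized_C, 4), "\n")
  cat("  basal:", sum(rowSums(x$adjacency) == 0),
      " Z =", x$Z, "\n")
  invisible(x)
}

#' Reassign consumer metabolic groups by a mass threshold
#'
#' By default all consumers are ectothermic invertebrates; this optionally
#' promotes consumers at or above a body-mass threshold to ectothermic
#' vertebrates, so that both consumer metabolism coefficients are exercised.
#'
#' @param web A `food_web` with masses assigned.
#' @param vertebrate_mass_threshold Mass at or above which a consumer is
#'   labelled `ecto_vertebrate` (default `Inf`: no promotion).
#' @return The web with `metabolic_group` updated.
#' @export
assign_metabolic_groups <- function(web, vertebrate_mass_threshold = Inf) {
  stopifnot(inherits(web, "food_web"), !is.null(web$mass))
  cons <- rowSums(web$adjacency) > 0
  grp <- ifelse(cons, "ecto_invertebrate", "producer")
  grp[cons & web$mass >= vertebrate_mass_threshold] <- "ecto_vertebrate"
  web$metabolic_group <- grp
  web
}
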