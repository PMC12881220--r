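#' Simulate a genus-level tree topology
#'
#' Random bifurcating topology with genus-style tip labels. Branch lengths
#' are irrelevant downstream (the pipeline overwrites them with Grafen
#' lengths), so only the topology is returned.
#'
#' @param n_tips Number of genera (>= 2).
#' @param seed Integer seed.
#' @param prefix Tip-label prefix.
#' @return A rooted `phylo` object without branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = 1, prefix = "genus") {
  stopifnot(n_tips >= 2)
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_tips, tip.label = paste0(prefix, "_",
                                                seq_len(n_tips)))
  tree$edge.length <- NULL
  tree
}

#' Generator settings for synthetic rate data
#'
#' Defaults emulate the structure of the compiled empirical dataset: true
#' intercepts equal to the published phylogenetic-model estimates, 3/4-law
#' slopes, phylogenetic signal lambda = 0.8 (within the 0.5-0.95 range the
#' fitted models report), masses spanning 10 orders of magnitude
#' (log10 kg in [-10, 5] at full width) and measurement temperatures
#' between -11.4 and 45 C for ectotherms, with endotherms at body
#' temperature.
#'
#' @param n_genera Number of genera.
#' @param C_true,b_true True intercept and slope on the working log scale.
#' @param lambda_true Pagel's lambda of the generated phylogenetic effects.
#' @param sigma_phylo,sigma_order,sigma_resid Standard deviations of the
#'   phylogenetic, Order and residual effects (log-scale units).
#' @param n_orders Number of Orders the genera are nested in.
#' @param n_families Number of Families (>= n_orders).
#' @param mass_range_log10 Range of log10 body mass in kg.
#' @param temp_range_C Measurement-temperature range for ectotherms.
#' @param rate_kind `"metabolism"` (ln scale) or `"production"` (log10).
#' @param metabolic_group Group label stamped on all records.
#' @param records_per_genus Integer range; each genus emits
#'   Uniform(min, max) records.
#' @param Ea Activation energy used to un-correct the generated rates.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_genera = 200, C_true = 16.65, b_true = 0.75,
                           lambda_true = 0.8, sigma_phylo = 1,
                           sigma_order = 0.5, sigma_resid = 0.5,
                           n_orders = 12, n_families = 30,
                           mass_range_log10 = c(-10, 5),
                           temp_range_C = c(-11.4, 45),
                           rate_kind = c("metabolism", "production"),
                           metabolic_group = "ecto_invertebrate",
                           records_per_genus = c(1, 5),
                           Ea = 0.63) {
  rate_kind <- match.arg(rate_kind)
  stopifnot(n_genera >= 3, sigma_phylo >= 0, sigma_order >= 0,
            sigma_resid >= 0, lambda_true >= 0, lambda_true <= 1,
            diff(mass_range_log10) > 0)
  structure(as.list(environment()), class = "generator_spec")
}

# contiguous blocks of tips in cladewise order approximate monophyletic
# Orders/Families for the nesting structure
block_assign <- function(n, k, prefix) {
  cut_id <- sort(rep_len(seq_len(k), n))
  paste0(prefix, "_", cut_id)
}

#' Simulate genus-level traits on a tree
#'
#' Inverts the phylogenetic hierarchical model: per genus a log mass is
#' drawn uniformly over the configured range; Order effects are iid
#' normal; phylogenetic effects are jointly multivariate normal with
#' covariance sigma_phylo^2 * V(lambda_true) built from the Grafen tree;
#' a genus-level residual is added; the genus's latent log corrected rate
#' is C_true + b_true * log mass + effects. Each emitted record then
#' un-corrects the rate by its own temperature (observed rate =
#' corrected * exp(-Ea / k T)), so the ingestion pipeline's Boltzmann
#' correction exactly restores the latent value.
#'
#' @param tree A `phylo` whose tips are the genera (Grafen lengths are
#'   computed internally).
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A list: `records` (a raw record table in the CSV dialect the
#'   ingestion step reads), `truth` (per-genus latent values), `tree`.
#' @export
simulate_traits <- function(tree, spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"), inherits(tree, "phylo"))
  set.seed(as.integer(seed))
  genera <- tree$tip.label
  n <- length(genera)
  treeg <- grafen_lengths(tree)
  V <- phylo_vcv(treeg)[genera, genera]
  Vl <- lambda_transform(V, spec$lambda_true)
  ev <- eigen((Vl + t(Vl)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("lambda-transformed covariance is not PSD")

  base <- if (spec$rate_kind == "metabolism") exp(1) else 10
  log_mass <- stats::runif(n, spec$mass_range_log10[1],
                           spec$mass_range_log10[2]) / log10(base)
  # mass range is specified in log10 kg; convert to the working log base
  orders <- block_assign(n, spec$n_orders, "order")
  families <- paste0(orders, ".",
                     block_assign(n, spec$n_families, "family"))
  u_order <- stats::rnorm(spec$n_orders, 0, spec$sigma_order)
  names(u_order) <- unique(orders)
  phylo_eff <- if (spec$sigma_phylo > 0) {
    drop(MASS::mvrnorm(1, rep(0, n), spec$sigma_phylo^2 * Vl))
  } else rep(0, n)
  resid <- stats::rnorm(n, 0, spec$sigma_resid)
  latent <- spec$C_true + spec$b_true * log_mass +
    u_order[orders] + phylo_eff + resid

  k <- physical_constants()$boltzmann_k
  endo <- spec$metabolic_group == "endo_vertebrate"
  recs <- lapply(seq_len(n), function(i) {
    nrec <- sample(seq(spec$records_per_genus[1],
                       spec$records_per_genus[2]), 1)
    if (endo) {
      is_bird <- stats::runif(nrec) < 0.5
      T_C <- ifelse(is_bird, 39, 37)
      cls <- ifelse(is_bird, "bird", "mammal")
    } else {
      T_C <- stats::runif(nrec, spec$temp_range_C[1], spec$temp_range_C[2])
      cls <- NA_character_
    }
    T_K <- celsius_to_kelvin(T_C)
    corrected <- base^latent[i]  # latent is on the log scale
    observed <- corrected * exp(-spec$Ea / (k * T_K))
    data.frame(
      genus = genera[i], family = families[i], order = orders[i],
      class = cls, metabolic_group = spec$metabolic_group,
      rate_kind = spec$rate_kind, rate_value = observed,
      rate_unit = if (spec$rate_kind == "metabolism") "W" else "kg_per_yr",
      mass_kg = base^log_mass[i], temperature_C = T_C,
      temperature_source = if (endo) "body" else "environment",
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  truth <- data.frame(genus = genera, order = orders, family = families,
                      log_mass = log_mass, latent_log_rate = latent,
                      phylo_eff = phylo_eff,
                      order_eff = unname(u_order[orders]),
                      resid = resid, stringsAsFactors = FALSE)
  list(records = records, truth = truth, tree = tree,
       spec = spec, seed = as.integer(seed))
}

#' Emulate the compiled multi-group rate dataset
#'
#' End-to-end fixture generator: one tree and one synthetic record table
#' per metabolic group for the requested rate kind, with group sizes
#' scaled down 10x from the empirical compilation (floored at 10 genera so
#' every group remains fittable) and true intercepts defaulting to the
#' published phylogenetic-model estimates.
#'
#' @param rate_kind `"metabolism"` or `"production"`.
#' @param scale Division factor on the empirical group sizes (default 10).
#' @param seed Integer seed.
#' @param ... Overrides forwarded to every group's [generator_spec()].
#' @return A named list (one element per metabolic group) of
#'   [simulate_traits()] outputs.
#' @export
emulate_compiled_dataset <- function(rate_kind = c("metabolism",
                                                   "production"),
                                     scale = 10, seed = 1, ...) {
  rate_kind <- match.arg(rate_kind)
  full_n <- if (rate_kind == "metabolism") {
    c(ecto_invertebrate = 552, ecto_vertebrate = 259,
      endo_vertebrate = 525)
  } else {
    c(producer = 19, ecto_invertebrate = 142, ecto_vertebrate = 46,
      endo_vertebrate = 798)
  }
  tab <- published_intercepts()
  tab <- tab[tab$rate_kind == rate_kind, ]
  C_true <- stats::setNames(tab$updated_intercept, tab$metabolic_group)
  out <- list()
  for (g in names(full_n)) {
    n <- max(10L, round(full_n[[g]] / scale))
    sp <- generator_spec(n_genera = n, C_true = C_true[[g]],
                         rate_kind = rate_kind, metabolic_group = g, ...)
    tree <- simulate_tree(n, seed = seed + match(g, names(full_n)),
                          prefix = paste0(substr(g, 1, 4), "_genus"))
    out[[g]] <- simulate_traits(tree, sp,
                                seed = seed + 100L * match(g, names(full_n)))
  }
  out
}
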