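# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

make_record_table <- function() {
  data.frame(
    genus = c("Apis", "Apis", "Mus", "Mus", "Corvus", "Rana"),
    family = c("Apidae", "Apidae", "Muridae", "Muridae", "Corvidae",
               "Ranidae"),
    order = c("Hymenoptera", "Hymenoptera", "Rodentia", "Rodentia",
              "Passeriformes", "Anura"),
    class = c(NA, NA, "mammal", "mammal", "bird", "amphibian"),
    metabolic_group = c("ecto_invertebrate", "ecto_invertebrate",
                        "endo_vertebrate", "endo_vertebrate",
                        "endo_vertebrate", "ecto_vertebrate"),
    rate_kind = "metabolism",
    rate_value = c(0.001, 0.002, 0.05, 0.5, 1.2, 0.01),
    rate_unit = c("W", "mlO2_per_s", "W", "W", "W", "W"),
    mass_kg = c(1e-4, 1e-4, 0.02, 0.02, 0.5, 0.05),
    temperature_C = c(25, 20, NA, 37, NA, 15),
    temperature_source = NA_character_,
    stringsAsFactors = FALSE
  )
}

# small genus table for direct fitting (no file round trip)
make_genus_table <- function(n = 60, C = 4, b = 0.75, sigma = 0.3,
                             seed = 1, n_orders = 6) {
  set.seed(seed)
  m <- runif(n, -8, 4)
  orders <- paste0("order_", rep_len(seq_len(n_orders), n))
  data.frame(genus = paste0("g", seq_len(n)), order = orders,
             family = orders,
             log_rate_corrected = C + b * m + rnorm(n, 0, sigma),
             log_mass = m, stringsAsFactors = FALSE)
}

# phylogenetically structured genus data plus its Grafen covariance
make_phylo_dataset <- function(n = 120, C = 5, b = 0.75, lambda = 0.8,
                               sigma_p = 1, sigma_o = 0.4, sigma_e = 0.3,
                               seed = 1) {
  tree <- simulate_tree(n, seed = seed)
  sp <- generator_spec(n_genera = n, C_true = C, b_true = b,
                       lambda_true = lambda, sigma_phylo = sigma_p,
                       sigma_order = sigma_o, sigma_resid = sigma_e)
  sim <- simulate_traits(tree, sp, seed = seed + 1000)
  gm <- genus_means(read_rate_table(sim$records))
  mt <- match_tree_table(gm, tree)
  V <- phylo_vcv(grafen_lengths(mt$tree))
  list(genus_table = mt$genus_table, V = V, tree = mt$tree, sim = sim)
}
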