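#' Run the factorial BEFW coefficient experiment
#'
#' Crosses connectance, species richness and predator-prey mass ratio
#' (defaults C in {0.05, 0.2}, SR in {40, 100}, Z in {10, 100}) with
#' seeded replicates. Each replicate generates one niche-model web and
#' runs the bioenergetic simulation once per coefficient set on that same
#' web with the same initial biomasses (a paired design), recording the
#' four response metrics per run. Failed simulations are logged and kept
#' as missing rows, not dropped.
#'
#' @param coefficient_sets Named list of `coefficient_set` objects (e.g.
#'   `list(Brose = legacy_coefficients(), updated = updated_coefficients())`).
#' @param n_reps Replicates per design cell (default 25; the full-scale
#'   design uses 100).
#' @param C_levels,SR_levels,Z_levels Factor levels of the design.
#' @param t_max,n_save Simulation horizon and save grid (see
#'   [simulate_befw()]).
#' @param base_seed Integer; every web and initial condition derives its
#'   seed from this.
#' @param ... Extra arguments passed to [befw_params()].
#' @return A data frame with one row per (cell, replicate, coefficient
#'   set): design columns, `seed`, the four metrics, and `failed`.
#' @export
run_design <- function(coefficient_sets, n_reps = 25,
                       C_levels = c(0.05, 0.2), SR_levels = c(40, 100),
                       Z_levels = c(10, 100), t_max = 500, n_save = 250,
                       base_seed = 1, ...) {
  stopifnot(is.list(coefficient_sets), length(coefficient_sets) >= 1)
  if (is.null(names(coefficient_sets)))
    names(coefficient_sets) <- vapply(coefficient_sets, `[[`, "", "label")
  cells <- expand.grid(C = C_levels, SR = SR_levels, Z = Z_levels,
                       rep = seq_len(n_reps))
  rows <- vector("list", nrow(cells) * length(coefficient_sets))
  ri <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    seed_i <- (as.integer(base_seed) + 7L * i) %% .Machine$integer.max
    web <- tryCatch(
      generate_niche_web(cell$SR, cell$C, seed = seed_i, Z = cell$Z),
      error = function(e) NULL)
    set.seed(seed_i + 1L)
    B0_init <- if (is.null(web)) NULL else stats::runif(cell$SR, 0.05, 1)
    for (lab in names(coefficient_sets)) {
      ri <- ri + 1L
      met <- list(persistence = NA_real_, total_biomass = NA_real_,
                  population_stability = NA_real_,
                  community_stability = NA_real_)
      failed <- TRUE
      if (!is.null(web)) {
        met_try <- tryCatch({
          pars <- befw_params(web, coefficient_sets[[lab]], ...)
          res <- simulate_befw(web, pars, B_init = B0_init,
                               t_max = t_max, n_save = n_save)
          befw_metrics(res)
        }, error = function(e) {
          message("simulation failed (", lab, ", cell ", i, "): ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(met_try)) { met <- met_try; failed <- FALSE }
      }
      rows[[ri]] <- data.frame(
        source = lab, C = cell$C, SR = cell$SR, Z = cell$Z,
        rep = cell$rep, seed = seed_i,
        persistence = met$persistence, total_biomass = met$total_biomass,
        population_stability = met$population_stability,
        community_stability = met$community_stability,
        failed = failed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type II ANOVA effect sizes for the coefficient experiment
#'
#' Fits `response ~ source + SR + C + Z + source:SR + source:C + source:Z`
#' (all predictors as factors), extracts Type II sums of squares, and
#' reports eta-squared (SS_term / SS_total, with SS_total the corrected
#' total sum of squares) together with partial eta-squared, F and p for
#' every term.
#'
#' @param results Result table from [run_design()].
#' @param response One of `"persistence"`, `"total_biomass"`,
#'   `"population_stability"`, `"community_stability"`.
#' @return A data frame: one row per model term with `sum_sq`, `df`, `F`,
#'   `p`, `eta2`, `eta2_partial`.
#' @export
anova_eta2 <- function(results, response = "persistence") {
  stopifnot(response %in% names(results))
  d <- results[!results$failed & is.finite(results[[response]]), ]
  d$y <- d[[response]]
  d$source <- factor(d$source)
  d$SR <- factor(d$SR); d$C <- factor(d$C); d$Z <- factor(d$Z)
  fit <- stats::lm(y ~ source + SR + C + Z +
                     source:SR + source:C + source:Z, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  a2 <- car::Anova(fit, type = 2)
  ss_total <- sum((d$y - mean(d$y))^2)
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  ss <- a2[terms, "Sum Sq"]
  ss_res <- a2["Residuals", "Sum Sq"]
  data.frame(term = terms, sum_sq = ss, df = a2[terms, "Df"],
             F = a2[terms, "F value"], p = a2[terms, "Pr(>F)"],
             eta2 = ss / ss_total,
             eta2_partial = ss / (ss + ss_res),
             row.names = NULL)
}
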