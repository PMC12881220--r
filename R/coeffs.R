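#' Critical temperature implied by the producer production intercept
#'
#' The BEFW timescale is anchored at the temperature at which the basal
#' producer's mass- and temperature-corrected production rate equals 1:
#' solving 10^Cp * exp(-Ea/(k T)) = 1 gives T = Ea / (k ln(10) Cp).
#'
#' @param producer_intercept_log10 Producer production intercept Cp in
#'   log10(kg/yr).
#' @param Ea Activation energy in eV (default 0.63).
#' @return Temperature in Kelvin.
#' @examples
#' t_critical(10.31)  # about 307.96 K (34.8 C)
#' @export
t_critical <- function(producer_intercept_log10, Ea = 0.63) {
  if (!is.numeric(producer_intercept_log10) ||
      any(producer_intercept_log10 <= 0))
    stop("producer intercept must be positive")
  k <- physical_constants()$boltzmann_k
  Ea / (k * log(10) * producer_intercept_log10)
}

#' Convert a metabolism intercept into a BEFW metabolism coefficient
#'
#' The intercept C_x (ln W at 1 kg, temperature-corrected) is mapped to the
#' dimensionless BEFW coefficient a_x by restoring the Boltzmann factor at
#' the model's reference temperature, multiplying by 3 to convert basal to
#' field metabolic rate, and by C_fac = 51.7 to convert Watts into kg of
#' biomass per year:
#' a_x = fmr * C_fac * exp(C_x - Ea/(k T_crit)).
#'
#' @param C_x_lnW Metabolism intercept in ln(W).
#' @param Ea Activation energy in eV.
#' @param T_crit Reference (critical) temperature in Kelvin; default
#'   307.75 K = 34.6 C.
#' @param C_fac Watts to kg-biomass-per-year conversion (default 51.7).
#' @param fmr Basal-to-field metabolic rate multiplier (default 3).
#' @return The coefficient a_x (dimensionless after timescale
#'   normalisation by the unit producer production rate).
#' @examples
#' metabolism_coefficient(16.65)  # about 0.127 -> printed 0.13
#' @export
metabolism_coefficient <- function(C_x_lnW, Ea = 0.63, T_crit = 307.75,
                                   C_fac = 51.7, fmr = 3) {
  stopifnot(is.numeric(C_x_lnW), Ea > 0, T_crit > 0, C_fac > 0, fmr > 0)
  k <- physical_constants()$boltzmann_k
  fmr * C_fac * exp(C_x_lnW - Ea / (k * T_crit))
}

#' Invert a metabolism coefficient back to its intercept
#'
#' @param a_x Coefficient from [metabolism_coefficient()].
#' @inheritParams metabolism_coefficient
#' @return The intercept C_x in ln(W).
#' @export
metabolism_intercept <- function(a_x, Ea = 0.63, T_crit = 307.75,
                                 C_fac = 51.7, fmr = 3) {
  k <- physical_constants()$boltzmann_k
  log(a_x / (fmr * C_fac)) + Ea / (k * T_crit)
}

#' Convert a production intercept into a BEFW production coefficient
#'
#' Production rates in the BEFW are normalised by the basal producer's
#' production rate at the critical temperature, which defines the model's
#' unit of time. In intercept form:
#' a_r = 10^(C_r - Ea/(k T ln 10)) / R_p with
#' R_p = 10^(C_p - Ea/(k T ln 10)), so the producer group maps to exactly 1.
#'
#' @param C_r_log10 Production intercept of the focal group, log10(kg/yr).
#' @param producer_intercept_log10 Producer production intercept Cp.
#' @param Ea Activation energy in eV.
#' @param T_crit Critical temperature in Kelvin.
#' @return The normalised production coefficient a_r (producer: exactly 1).
#' @export
production_coefficient <- function(C_r_log10, producer_intercept_log10,
                                   Ea = 0.63, T_crit = 307.75) {
  stopifnot(is.numeric(C_r_log10), is.numeric(producer_intercept_log10),
            Ea > 0, T_crit > 0)
  # the Boltzmann term cancels in the ratio; kept explicit for clarity
  10^(C_r_log10 - producer_intercept_log10)
}

#' Assemble a labelled BEFW coefficient set from intercepts
#'
#' Applies [metabolism_coefficient()] to the consumer metabolism intercepts
#' and [production_coefficient()] to the production intercepts, producing
#' the parameter set a BEFW simulation consumes. Consumer production
#' coefficients are computed but flagged as not directly comparable to
#' published values (none were published).
#'
#' @param metabolism_intercepts Named numeric vector of intercepts in ln(W)
#'   for (a subset of) `ecto_invertebrate`, `ecto_vertebrate`,
#'   `endo_vertebrate`.
#' @param production_intercepts Named numeric vector in log10(kg/yr); must
#'   include `producer` if non-empty.
#' @param label Provenance label, e.g. `"updated"`, `"Brose"`.
#' @param Ea,T_crit,C_fac,fmr Constants of the conversion chain.
#' @param exponents Named list/vector of allometric exponents b per group
#'   (default 0.75 for all groups).
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(metabolism_intercepts,
                            production_intercepts = c(producer = NA_real_),
                            label = "custom",
                            Ea = 0.63, T_crit = 307.75,
                            C_fac = 51.7, fmr = 3,
                            exponents = NULL) {
  a_x <- metabolism_coefficient(metabolism_intercepts, Ea = Ea,
                                T_crit = T_crit, C_fac = C_fac, fmr = fmr)
  a_r <- NULL
  if (!all(is.na(production_intercepts))) {
    if (!"producer" %in% names(production_intercepts))
      stop("production intercepts must include the producer group")
    Cp <- production_intercepts[["producer"]]
    a_r <- production_coefficient(production_intercepts, Cp,
                                  Ea = Ea, T_crit = T_crit)
  }
  if (is.null(exponents)) {
    exponents <- stats::setNames(rep(0.75, 4), metabolic_groups())
  }
  structure(list(
    label = label,
    a_x = a_x,
    a_r = a_r,
    exponents = exponents,
    metabolism_intercepts = metabolism_intercepts,
    production_intercepts = production_intercepts,
    constants = list(Ea = Ea, T_crit = T_crit, C_fac = C_fac, fmr = fmr)
  ), class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("BEFW coefficient set [", x$label, "]\n", sep = "")
  cat("  constants: Ea =", x$constants$Ea, "eV, T_crit =",
      x$constants$T_crit, "K, C_fac =", x$constants$C_fac,
      ", FMR x", x$constants$fmr, "\n")
  cat("  a_x:\n")
  print(round(x$a_x, 4))
  if (!is.null(x$a_r)) {
    cat("  a_r (producer-normalised; consumer values not comparable to",
        "published sets):\n")
    print(round(x$a_r, 4))
  }
  invisible(x)
}

#' Legacy (Brose-style) coefficient set
#'
#' Recomputes the currently accepted coefficients from the legacy consumer
#' metabolism intercepts using the legacy constants Ea = 0.6 eV and
#' T_critical = 24.883 C = 298.033 K.
#'
#' @param metabolism_intercepts Named intercepts in ln(W); defaults to the
#'   published legacy intercepts (17.17, 18.18, 19.5).
#' @param production_intercepts Named production intercepts in log10(kg/yr).
#' @param Ea,T_crit Legacy constants.
#' @return A `coefficient_set` labelled `"Brose"`.
#' @export
legacy_coefficients <- function(
    metabolism_intercepts = c(ecto_invertebrate = 17.17,
                              ecto_vertebrate = 18.18,
                              endo_vertebrate = 19.5),
    production_intercepts = c(producer = 10.15),
    Ea = 0.6, T_crit = 298.033) {
  coefficient_set(metabolism_intercepts, production_intercepts,
                  label = "Brose", Ea = Ea, T_crit = T_crit)
}

#' Updated coefficient set from the published intercept table
#'
#' Builds the updated coefficient set from the published
#' phylogenetic-model intercepts, using Ea = 0.63 eV and T_critical =
#' 34.6 C = 307.75 K.
#'
#' @return A `coefficient_set` labelled `"updated"`.
#' @export
updated_coefficients <- function() {
  tab <- published_intercepts()
  met <- tab[tab$rate_kind == "metabolism", ]
  pro <- tab[tab$rate_kind == "production", ]
  coefficient_set(
    stats::setNames(met$updated_intercept, met$metabolic_group),
    stats::setNames(pro$updated_intercept, pro$metabolic_group),
    label = "updated", Ea = 0.63, T_crit = 307.75)
}

#' Published intercepts and coefficients (comparison table)
#'
#' Returns the published comparison of allometric intercepts and
#' coefficients across the legacy and updated estimation pipelines, bundled
#' as plain text with the package.
#'
#' @return A data frame with one row per rate kind x metabolic group.
#' @export
published_intercepts <- function() {
  path <- system.file("extdata", "published_coefficients.csv",
                      package = "allomcoef", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
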