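#' Convert an oxygen-consumption rate to power
#'
#' Rates reported as oxygen consumption are converted to Watts with the
#' standard oxycalorific equivalent of 20 J per mL O2, so a rate in mL O2
#' per second maps directly to J/s = W.
#'
#' @param rate_mlO2_per_s Non-negative rate in mL O2 per second.
#' @return Power in Watts.
#' @examples
#' o2_to_watts(1)    # 20 W
#' o2_to_watts(0.05) # 1 W
#' @export
o2_to_watts <- function(rate_mlO2_per_s) {
  if (any(!is.finite(rate_mlO2_per_s)) || any(rate_mlO2_per_s < 0))
    stop("oxygen consumption rate must be finite and non-negative")
  rate_mlO2_per_s * physical_constants()$joules_per_ml_O2
}

#' Boltzmann temperature correction of a biological rate
#'
#' Multiplies a rate by exp(Ea / (k T)), removing the Boltzmann-Arrhenius
#' temperature dependence so that rates measured at different temperatures
#' are standardised before allometric fitting. The inverse operation
#' (restoring the temperature dependence) is division by the same factor.
#'
#' @param rate Positive rate (any units; units are preserved).
#' @param temperature_K Measurement (or body) temperature in Kelvin.
#' @param Ea Activation energy in eV (default 0.63).
#' @return The temperature-corrected rate, same units as `rate`.
#' @examples
#' temperature_correct(1, 307.75)          # approx 2.07e10
#' temperature_correct(1, 300, Ea = 0)     # 1, any T
#' @export
temperature_correct <- function(rate, temperature_K, Ea = 0.63) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("temperature must be positive Kelvin")
  k <- physical_constants()$boltzmann_k
  rate * exp(Ea / (k * temperature_K))
}

#' Resolve measurement temperatures, filling endotherm defaults
#'
#' Endotherm records with a missing temperature receive the default body
#' temperature for their taxonomic class (mammals 37 C = 310.15 K, birds
#' 39 C = 312.15 K). Ectotherm or producer records with a missing
#' temperature cannot be corrected and are flagged for exclusion.
#'
#' @param metabolic_group Character vector of metabolic groups (see
#'   [metabolic_groups()] for levels).
#' @param temperature_K Numeric vector of temperatures in Kelvin, `NA` where
#'   missing.
#' @param class Taxonomic class used to pick the endotherm default; values
#'   containing "bird"/"aves" (case-insensitive) get the bird default,
#'   anything else the mammal default.
#' @return A list with `temperature_K` (defaults filled) and `drop` (logical
#'   vector: TRUE where the record has no usable temperature).
#' @export
resolve_temperature <- function(metabolic_group, temperature_K,
                                class = rep(NA_character_,
                                            length(metabolic_group))) {
  stopifnot(length(temperature_K) == length(metabolic_group),
            length(class) == length(metabolic_group))
  pc <- physical_constants()
  endo <- metabolic_group == "endo_vertebrate"
  missing_T <- !is.finite(temperature_K)
  is_bird <- grepl("bird|aves", class, ignore.case = TRUE)
  fill <- endo & missing_T
  temperature_K[fill] <- ifelse(is_bird[fill],
                                pc$bird_body_temp_K, pc$mammal_body_temp_K)
  drop <- missing_T & !endo
  list(temperature_K = temperature_K, drop = drop)
}

#' Read a rate-measurement table
#'
#' Reads a delimited file (or takes a data frame) of per-record rate
#' measurements and returns a validated `rate_table`. Rates reported in mL
#' O2 per second are converted to Watts; temperatures arrive in Celsius and
#' are converted to Kelvin; endotherms with missing temperatures receive
#' class defaults. Records with non-positive mass or rate, a missing genus,
#' an invalid metabolic group, or an unresolvable temperature are dropped
#' with a message reporting the count.
#'
#' Expected columns: `genus`, `metabolic_group`, `rate_kind`, `rate_value`,
#' `rate_unit` (one of `"W"`, `"mlO2_per_s"`, `"kg_per_yr"`), `mass_kg`,
#' `temperature_C`; optional: `family`, `order`, `class`,
#' `temperature_source`. Unknown columns are preserved and ignored.
#'
#' @param x Path to a CSV/TSV file, or a data frame with the columns above.
#' @param Ea Activation energy (eV) used for the Boltzmann correction.
#' @param sep Field separator when `x` is a path (default `","`).
#' @return A data frame of class `rate_table` with added columns
#'   `temperature_K`, `rate_W_or_kgyr` (unit-normalised rate) and
#'   `rate_corrected` (Boltzmann-corrected rate).
#' @export
read_rate_table <- function(x, Ea = 0.63, sep = ",") {
  df <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  required <- c("genus", "metabolic_group", "rate_kind", "rate_value",
                "rate_unit", "mass_kg", "temperature_C")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (opt in c("family", "order", "class", "temperature_source"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_

  bad_group <- !df$metabolic_group %in% metabolic_groups()
  bad_kind  <- !df$rate_kind %in% c("metabolism", "production")
  bad_unit  <- !df$rate_unit %in% c("W", "mlO2_per_s", "kg_per_yr")
  if (any(bad_group | bad_kind | bad_unit))
    stop("invalid metabolic_group / rate_kind / rate_unit values present")
  if (any(df$metabolic_group == "producer" & df$rate_kind == "metabolism"))
    stop("producer metabolism records are out of scope")

  # unit normalisation: everything in W (metabolism) or kg/yr (production)
  rate <- df$rate_value
  is_o2 <- df$rate_unit == "mlO2_per_s"
  rate[is_o2] <- o2_to_watts(pmax(rate[is_o2], 0))
  df$rate_W_or_kgyr <- rate

  df$temperature_K <- celsius_to_kelvin(df$temperature_C)
  res <- resolve_temperature(df$metabolic_group, df$temperature_K, df$class)
  df$temperature_K <- res$temperature_K
  if (is.null(df$temperature_source) || all(is.na(df$temperature_source))) {
    df$temperature_source <- ifelse(
      !is.finite(df$temperature_C),
      "default", ifelse(df$metabolic_group == "endo_vertebrate",
                        "body", "environment"))
  }

  drop <- res$drop |
    !is.finite(df$rate_W_or_kgyr) | df$rate_W_or_kgyr <= 0 |
    !is.finite(df$mass_kg) | df$mass_kg <= 0 |
    is.na(df$genus) | df$genus == ""
  if (any(drop))
    message(sum(drop), " record(s) dropped (non-positive rate/mass, ",
            "missing genus, or unresolvable temperature)")
  df <- df[!drop, , drop = FALSE]

  df$rate_corrected <- temperature_correct(df$rate_W_or_kgyr,
                                           df$temperature_K, Ea = Ea)
  class(df) <- c("rate_table", "data.frame")
  attr(df, "Ea") <- Ea
  df
}

#' Genus-level means of log-transformed corrected rates and masses
#'
#' Collapses a `rate_table` to one row per genus x rate kind, averaging on
#' the log scale (a geometric mean of rates and masses), the scale on which
#' the allometric regressions are fitted. Metabolism uses natural logs
#' (intercepts in ln W); production uses base-10 logs (intercepts in
#' log10 kg/yr).
#'
#' @param table A `rate_table` from [read_rate_table()].
#' @return A data frame with one row per (genus, rate_kind): columns
#'   `genus`, `family`, `order`, `metabolic_group`, `rate_kind`, `n_records`,
#'   `log_rate_corrected`, `log_mass`, `log_base`.
#' @export
genus_means <- function(table) {
  stopifnot(all(c("genus", "metabolic_group", "rate_kind",
                  "rate_corrected", "mass_kg") %in% names(table)))
  # a genus must not span metabolic groups within a rate kind
  chk <- unique(table[, c("genus", "rate_kind", "metabolic_group")])
  dup <- duplicated(chk[, c("genus", "rate_kind")])
  if (any(dup))
    stop("genus assigned to more than one metabolic group: ",
         paste(unique(chk$genus[dup]), collapse = ", "))

  key <- interaction(table$genus, table$rate_kind, drop = TRUE)
  base_log <- ifelse(table$rate_kind == "metabolism", exp(1), 10)
  lr <- log(table$rate_corrected, base = base_log)
  lm_ <- log(table$mass_kg, base = base_log)
  first <- function(x) x[1]
  out <- data.frame(
    genus = tapply(table$genus, key, first),
    family = tapply(as.character(table$family), key, first),
    order = tapply(as.character(table$order), key, first),
    metabolic_group = tapply(table$metabolic_group, key, first),
    rate_kind = tapply(table$rate_kind, key, first),
    n_records = as.integer(tapply(lr, key, length)),
    log_rate_corrected = as.numeric(tapply(lr, key, mean)),
    log_mass = as.numeric(tapply(lm_, key, mean)),
    stringsAsFactors = FALSE
  )
  out$log_base <- ifelse(out$rate_kind == "metabolism", "ln", "log10")
  rownames(out) <- NULL
  out[order(out$rate_kind, out$genus), , drop = FALSE]
}
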