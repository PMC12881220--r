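#' Serialise a coefficient set to JSON
#'
#' @param coeffs A `coefficient_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficient_set <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  jsonlite::write_json(
    list(label = coeffs$label, a_x = as.list(coeffs$a_x),
         a_r = as.list(coeffs$a_r), exponents = as.list(coeffs$exponents),
         metabolism_intercepts = as.list(coeffs$metabolism_intercepts),
         production_intercepts = as.list(coeffs$production_intercepts),
         constants = coeffs$constants),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coefficient set from JSON
#'
#' @param path File written by [write_coefficient_set()].
#' @return A `coefficient_set`.
#' @export
read_coefficient_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefficient_set(unlist(j$metabolism_intercepts),
                  unlist(j$production_intercepts),
                  label = j$label,
                  Ea = j$constants$Ea, T_crit = j$constants$T_crit,
                  C_fac = j$constants$C_fac, fmr = j$constants$fmr,
                  exponents = unlist(j$exponents))
}

#' Export a phylogenetic covariance matrix as delimited text
#'
#' @param V Covariance matrix with tip-name dimnames.
#' @param path Output path (tab-separated, tip order in the header).
#' @return `path`, invisibly.
#' @export
write_vcv <- function(V, path) {
  utils::write.table(data.frame(tip = rownames(V), V, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a food web to JSON
#'
#' @param web A `food_web`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_web <- function(web, path) {
  stopifnot(inherits(web, "food_web"))
  edges <- which(web$adjacency == 1, arr.ind = TRUE)
  jsonlite::write_json(
    list(S = web$S, target_C = web$target_C,
         realized_C = web$realized_C, Z = web$Z, seed = web$seed,
         consumer = edges[, 1], resource = edges[, 2],
         mass = web$mass, trophic_level = web$trophic_level,
         metabolic_group = web$metabolic_group),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a food web from JSON
#'
#' @param path File written by [write_food_web()].
#' @return A `food_web`.
#' @export
read_food_web <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(0L, j$S, j$S)
  A[cbind(j$consumer, j$resource)] <- 1L
  structure(list(S = j$S, adjacency = A, niche = NULL,
                 target_C = j$target_C, realized_C = j$realized_C,
                 trophic_level = j$trophic_level, Z = j$Z, mass = j$mass,
                 metabolic_group = j$metabolic_group,
                 seed = j$seed), class = "food_web")
}

#' Write a run manifest
#'
#' Records the configuration, seeds and package version of an analysis
#' run so every artifact is regenerable from its manifest.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seeds Named list/vector of seeds used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list()) {
  jsonlite::write_json(
    list(package = "allomcoef",
         version = as.character(utils::packageVersion("allomcoef")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, seeds = seeds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
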