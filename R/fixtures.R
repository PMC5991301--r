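#' @include community-data.R
NULL

#' Packaged oribatid mite survey: pooled annual abundances
#'
#' Pooled annual abundances (individuals per kg dry weight) of 61 adult
#' oribatid mite taxa in the three microhabitats moss, dead wood and
#' litter, from a published year-long monthly survey of a temperate
#' oak-mixed forest floor. This is the canonical worked example for the
#' network indices: its pooled bipartite network is highly generalized.
#'
#' @return data.frame with columns `taxon`, `moss`, `dead_wood`, `litter`.
#' @seealso [oribatidPooledNetwork()], [oribatidMonthlyConditions()]
#' @export
oribatidPooledAbundance <- function() {
  path <- system.file("extdata", "oribatid_pooled_ind_per_kg.csv",
                      package = "microspec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged oribatid survey as an InteractionMatrix
#'
#' The pooled taxon-by-microhabitat network of the packaged oribatid
#' survey (see [oribatidPooledAbundance()]), ready for [h2Prime()],
#' [dPrime()] and friends.
#'
#' @param valueMode `"density"` (Ind/kg, default) or `"count"` (the same
#'   densities rounded to integers, for randomization tests).
#' @return an [InteractionMatrix-class].
#' @export
oribatidPooledNetwork <- function(valueMode = c("density", "count")) {
  valueMode <- match.arg(valueMode)
  df <- oribatidPooledAbundance()
  v <- as.matrix(df[, c("moss", "dead_wood", "litter")])
  rownames(v) <- df$taxon
  if (valueMode == "count") v <- round(v)
  interactionMatrix(v, valueMode = valueMode)
}

#' Packaged oribatid survey: monthly conditions and network indices
#'
#' Monthly weather summaries (air temperature and relative humidity,
#' mean +/- SD over the five days preceding each sampling date) together
#' with the monthly network indices (H2' of the monthly networks and d'
#' per microhabitat) of the packaged oribatid survey. The standard input
#' for the monthly association statistics.
#'
#' @return data.frame with columns `month`, `temp_mean`, `temp_sd`,
#'   `rh_mean`, `rh_sd`, `h2_prime`, `dprime_dead_wood`, `dprime_litter`,
#'   `dprime_moss`.
#' @export
oribatidMonthlyConditions <- function() {
  path <- system.file("extdata", "oribatid_monthly_conditions.csv",
                      package = "microspec", mustWork = TRUE)
  utils::read.csv(path)
}
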