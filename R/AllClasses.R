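#' @include AllGenerics.R
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' CommunityDataset: long-format community survey data
#'
#' Container for a long-format community survey: one row per
#' (taxon, microhabitat, month, replicate) sample cell, holding the raw
#' individual count, the sample dry weight in kilograms, and the derived
#' density in individuals per kg dry weight (Ind/kg). Densities make samples
#' of different physical size comparable and are the standard currency of
#' the downstream analyses.
#'
#' @slot records `data.frame` with columns `taxon`, `microhabitat`, `month`,
#'   `replicate`, `raw_count`, `dry_weight_kg`, `density`.
#' @slot taxa character, the ordered distinct taxon labels present.
#' @slot habitats character, the ordered distinct microhabitat labels.
#' @slot months integer, the ordered distinct months (1-12) present.
#'
#' @seealso [readSurveyTable()], [buildInteractionMatrix()],
#'   [generateCommunity()]
#' @export
setClass("CommunityDataset",
  representation(
    records = "data.frame",
    taxa = "character",
    habitats = "character",
    months = "integer"
  )
)

setValidity("CommunityDataset", function(object) {
  rec <- object@records
  req <- c("taxon", "microhabitat", "month", "replicate", "raw_count",
           "dry_weight_kg", "density")
  miss <- setdiff(req, names(rec))
  if (length(miss) > 0)
    return(sprintf("records is missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(rec) == 0) return("records must contain at least one row")
  if (any(rec$raw_count < 0)) return("raw_count must be >= 0")
  if (any(rec$dry_weight_kg <= 0)) return("dry_weight_kg must be > 0")
  if (any(rec$month < 1 | rec$month > 12)) return("month must lie in 1..12")
  if (any(abs(rec$density - rec$raw_count / rec$dry_weight_kg) >
          1e-8 * pmax(1, rec$density)))
    return("density must equal raw_count / dry_weight_kg")
  key <- paste(rec$taxon, rec$microhabitat, rec$month, rec$replicate, sep = "\r")
  if (anyDuplicated(key))
    return("(taxon, microhabitat, month, replicate) combinations must be unique")
  if (!setequal(object@taxa, unique(rec$taxon)))
    return("taxa slot must list exactly the distinct taxon labels present")
  if (!setequal(object@habitats, unique(rec$microhabitat)))
    return("habitats slot must list exactly the distinct microhabitat labels")
  if (!setequal(object@months, unique(rec$month)))
    return("months slot must list exactly the distinct months present")
  TRUE
})

#' InteractionMatrix: weighted taxon-by-microhabitat network
#'
#' Nonnegative weighted bipartite matrix `a[i, j]` (taxon i, microhabitat j)
#' with its margins: row totals `A_i`, column totals `B_j` and grand total
#' `m`. All network indices of the package (H2', d', link temperature,
#' null models) operate on this container. `valueMode` records whether the
#' weights are densities (Ind/kg) or raw counts; null models require counts
#' (densities are rounded to the nearest integer when randomized).
#'
#' @slot values numeric matrix, taxa in rows, microhabitats in columns.
#' @slot rowTotals,colTotals,grandTotal the margins (recomputed, not trusted).
#' @slot valueMode `"density"` or `"count"`.
#'
#' @seealso [buildInteractionMatrix()], [interactionMatrix()], [h2Prime()],
#'   [dPrime()], [nullTestH2()]
#' @export
setClass("InteractionMatrix",
  representation(
    values = "matrix",
    rowTotals = "numeric",
    colTotals = "numeric",
    grandTotal = "numeric",
    valueMode = "character"
  )
)

setValidity("InteractionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (any(v < 0)) return("all interaction weights must be >= 0")
  if (sum(v) <= 0) return("grand total must be > 0")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry taxon rownames and habitat colnames")
  if (!isTRUE(all.equal(unname(object@rowTotals), unname(rowSums(v)))))
    return("rowTotals must equal rowSums(values)")
  if (!isTRUE(all.equal(unname(object@colTotals), unname(colSums(v)))))
    return("colTotals must equal colSums(values)")
  if (!isTRUE(all.equal(object@grandTotal, sum(v))))
    return("grandTotal must equal sum(values)")
  if (!object@valueMode %in% c("density", "count"))
    return("valueMode must be 'density' or 'count'")
  TRUE
})

#' SpecializationResult: network-level complementary specialization
#'
#' Result of standardizing the two-dimensional Shannon entropy of an
#' interaction matrix between its margin-constrained extrema:
#' `h2Prime = (h2Max - h2) / (h2Max - h2Min)`, in `[0, 1]`;
#' 0 = maximally generalized (independence), 1 = maximally specialized.
#' The degenerate case `h2Max == h2Min` (no freedom under the margins)
#' yields 0 with `degenerate = TRUE`.
#'
#' @slot h2 observed two-dimensional Shannon entropy (nats).
#' @slot h2Min,h2Max entropy extrema under the fixed margins.
#' @slot h2Prime standardized index in `[0, 1]`.
#' @slot mode `"continuous"` or `"integer"` extremum heuristics.
#' @slot degenerate logical flag for `h2Max == h2Min`.
#' @export
setClass("SpecializationResult",
  representation(
    h2 = "numeric", h2Min = "numeric", h2Max = "numeric",
    h2Prime = "numeric", mode = "character", degenerate = "logical"
  )
)

setValidity("SpecializationResult", function(object) {
  tol <- 1e-9
  if (object@h2 < object@h2Min - 1e-6 || object@h2 > object@h2Max + 1e-6)
    return("h2 must lie within [h2Min, h2Max]")
  if (object@h2Prime < -tol || object@h2Prime > 1 + tol)
    return("h2Prime must lie in [0, 1]")
  TRUE
})

#' NodeSpecialization: node-level exclusiveness d'
#'
#' Standardized Kullback-Leibler divergence of one node's partner-use
#' distribution against overall partner availability. For a microhabitat
#' column h: `d = sum p'_j log(p'_j / q_j)` with `p'_j = a[j, h] / B_h` and
#' `q_j = A_j / m`; `dPrime = (d - dMin) / (dMax - dMin)` in `[0, 1]`.
#'
#' @slot node the habitat label.
#' @slot d raw KL divergence (nats).
#' @slot dMin,dMax standardization bounds.
#' @slot dPrime standardized index in `[0, 1]`.
#' @slot mode `"continuous"` or `"integer"`.
#' @slot degenerate logical, `TRUE` when `dMax == dMin`.
#' @export
setClass("NodeSpecialization",
  representation(
    node = "character", d = "numeric", dMin = "numeric", dMax = "numeric",
    dPrime = "numeric", mode = "character", degenerate = "logical"
  )
)

setValidity("NodeSpecialization", function(object) {
  tol <- 1e-9
  if (object@d < -tol) return("d must be >= 0")
  if (object@dPrime < -tol || object@dPrime > 1 + tol)
    return("dPrime must lie in [0, 1]")
  TRUE
})

#' NullEnsemble: observed statistic with its randomization null
#'
#' An observed statistic together with the draws of its null distribution,
#' the permutation p-value (add-one estimator, so never exactly 0), the
#' number of iterations and the seed that produced the draws. The
#' `alternative` slot documents which tail(s) the p-value integrates.
#'
#' @slot statistic name of the statistic (e.g. `"h2prime"`, `"mu"`).
#' @slot observed observed value.
#' @slot nullDraws numeric vector of null values.
#' @slot pValue permutation p-value in `(0, 1]`.
#' @slot nIter number of randomizations.
#' @slot seed integer seed (NA when the caller did not fix one).
#' @slot alternative `"greater"`, `"less"` or `"two.sided"`.
#' @export
setClass("NullEnsemble",
  representation(
    statistic = "character", observed = "numeric", nullDraws = "numeric",
    pValue = "numeric", nIter = "integerOrNumeric", seed = "integerOrNumeric",
    alternative = "character"
  )
)

setValidity("NullEnsemble", function(object) {
  if (length(object@pValue) != 1 || is.na(object@pValue))
    return("pValue must be a single non-NA value")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  if (length(object@nullDraws) != object@nIter)
    return("nullDraws must hold nIter values")
  TRUE
})

#' LinkTemperatureMatrix: standardized deviations from neutrality
#'
#' Per-cell standardized deviation of the observed interaction strength
#' from the neutral margin-product expectation `E[i, j] = A_i * B_j / m`.
#' Methods: `"relative"` `(a - E) / E`, `"raw"` `a - E`, `"z_null"`
#' `(a - mean_null) / sd_null` over fixed-margin randomizations.
#'
#' @slot expected neutral expectation matrix, summing to the grand total.
#' @slot t standardized deviation matrix.
#' @slot method the standardization used.
#' @export
setClass("LinkTemperatureMatrix",
  representation(expected = "matrix", t = "matrix", method = "character")
)

setValidity("LinkTemperatureMatrix", function(object) {
  if (!identical(dim(object@expected), dim(object@t)))
    return("expected and t must share dimensions")
  if (!object@method %in% c("relative", "raw", "z_null"))
    return("method must be one of 'relative', 'raw', 'z_null'")
  TRUE
})

#' NetworkCorrelation: correlation of two monthly networks
#'
#' Pearson correlation of the link-temperature cells of two networks,
#' restricted to their shared taxa. `rObs` is the observed correlation;
#' `rMean`/`rSd` summarize bootstrap resamples of the shared taxa; the
#' two-sided `pValue` comes from a fixed-margin (Patefield) null on the
#' second network.
#'
#' @slot monthPair character of length 2 naming the compared networks.
#' @slot rObs,rMean,rSd observed and bootstrap-summarized correlation.
#' @slot pValue two-sided permutation p-value.
#' @slot nPerm number of null permutations.
#' @slot nShared number of shared taxa used.
#' @slot method link-temperature method.
#' @slot seed integer seed (NA if unset).
#' @export
setClass("NetworkCorrelation",
  representation(
    monthPair = "character", rObs = "numeric", rMean = "numeric",
    rSd = "numeric", pValue = "numeric", nPerm = "integerOrNumeric",
    nShared = "integerOrNumeric", method = "character",
    seed = "integerOrNumeric"
  )
)

setValidity("NetworkCorrelation", function(object) {
  if (abs(object@rObs) > 1 + 1e-9) return("rObs must lie in [-1, 1]")
  if (!is.na(object@rMean) && abs(object@rMean) > 1 + 1e-9)
    return("rMean must lie in [-1, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' NicheEstimate: abundance-weighted environmental occurrence niche
#'
#' For one taxon and one environmental variable: the abundance-weighted
#' mean `mu = sum_m p_m * env_m` over the 12 months (`p_m` = share of the
#' taxon's annual abundance found in month m), the weighted SD as niche
#' breadth, the monthly proportion vector, the permutation p-value and the
#' response category.
#'
#' @slot taxon taxon label.
#' @slot variable `"temperature"` or `"humidity"`.
#' @slot mu abundance-weighted mean (deg C or %RH).
#' @slot breadth abundance-weighted SD (same units).
#' @slot pMonthly length-12 proportion vector summing to 1.
#' @slot monthsPresent number of months with positive abundance.
#' @slot pValue two-sided permutation p (NA when untested).
#' @slot category `"warmer"|"colder"|"neutral"|"none"` (temperature) or
#'   `"wetter"|"drier"|"neutral"|"none"` (humidity).
#' @slot reliable FALSE when the taxon occurs in fewer than 2 months.
#' @export
setClass("NicheEstimate",
  representation(
    taxon = "character", variable = "character", mu = "numeric",
    breadth = "numeric", pMonthly = "numeric",
    monthsPresent = "integerOrNumeric", pValue = "numeric",
    category = "character", reliable = "logical"
  )
)

setValidity("NicheEstimate", function(object) {
  if (abs(sum(object@pMonthly) - 1) > 1e-6)
    return("pMonthly must sum to 1")
  if (any(object@pMonthly < -1e-12)) return("pMonthly must be nonnegative")
  if (object@breadth < -1e-12) return("breadth must be >= 0")
  TRUE
})

## ---- accessors ----

#' @rdname accessors
#' @export
setMethod("records", "CommunityDataset", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("taxa", "CommunityDataset", function(x) x@taxa)

#' @rdname accessors
#' @export
setMethod("habitats", "CommunityDataset", function(x) x@habitats)

#' @rdname accessors
#' @export
setMethod("surveyMonths", "CommunityDataset", function(x) x@months)

#' @rdname accessors
#' @export
setMethod("taxa", "InteractionMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("habitats", "InteractionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("interactionValues", "InteractionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("rowTotals", "InteractionMatrix", function(x) x@rowTotals)

#' @rdname accessors
#' @export
setMethod("colTotals", "InteractionMatrix", function(x) x@colTotals)

#' @rdname accessors
#' @export
setMethod("grandTotal", "InteractionMatrix", function(x) x@grandTotal)

#' @rdname accessors
#' @export
setMethod("valueMode", "InteractionMatrix", function(x) x@valueMode)

#' @rdname accessors
#' @export
setMethod("nullDraws", "NullEnsemble", function(x) x@nullDraws)

#' @rdname accessors
#' @export
setMethod("pValue", "NullEnsemble", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("pValue", "NetworkCorrelation", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("pValue", "NicheEstimate", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("specializationIndex", "SpecializationResult", function(x) x@h2Prime)

#' @rdname accessors
#' @export
setMethod("specializationIndex", "NodeSpecialization", function(x) x@dPrime)

## ---- show methods ----

setMethod("show", "CommunityDataset", function(object) {
  cat(sprintf(
    "CommunityDataset: %d records | %d taxa x %d microhabitats x %d months\n",
    nrow(object@records), length(object@taxa), length(object@habitats),
    length(object@months)))
  cat("  microhabitats:", paste(object@habitats, collapse = ", "), "\n")
  cat("  months:", paste(object@months, collapse = ", "), "\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix: %d taxa x %d habitats (%s mode), m = %g\n",
              nrow(object@values), ncol(object@values), object@valueMode,
              object@grandTotal))
  cat("  column totals:",
      paste(sprintf("%s = %g", colnames(object@values), object@colTotals),
            collapse = ", "), "\n")
})

setMethod("show", "SpecializationResult", function(object) {
  cat(sprintf("H2' = %.4f  (H2 = %.4f in [%.4f, %.4f], %s mode%s)\n",
              object@h2Prime, object@h2, object@h2Min, object@h2Max,
              object@mode,
              if (object@degenerate) ", degenerate margins" else ""))
})

setMethod("show", "NodeSpecialization", function(object) {
  cat(sprintf("d'(%s) = %.4f  (d = %.4f in [%.4f, %.4f], %s mode)\n",
              object@node, object@dPrime, object@d, object@dMin, object@dMax,
              object@mode))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf(
    "NullEnsemble '%s': observed = %.4f, null mean = %.4f, p = %.4g (%s, n = %d)\n",
    object@statistic, object@observed, mean(object@nullDraws), object@pValue,
    object@alternative, as.integer(object@nIter)))
})

setMethod("show", "NetworkCorrelation", function(object) {
  cat(sprintf(
    "NetworkCorrelation %s ~ %s: r = %.3f (boot %.3f +/- %.3f), p = %.4g, %d shared taxa\n",
    object@monthPair[1], object@monthPair[2], object@rObs, object@rMean,
    object@rSd, object@pValue, as.integer(object@nShared)))
})

setMethod("show", "NicheEstimate", function(object) {
  cat(sprintf(
    "NicheEstimate %s (%s): mu = %.2f, breadth = %.2f, months = %d, p = %s, category = %s\n",
    object@taxon, object@variable, object@mu, object@breadth,
    as.integer(object@monthsPresent),
    ifelse(is.na(object@pValue), "NA", sprintf("%.4g", object@pValue)),
    object@category))
})
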