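#' @include community-data.R
NULL

#' Monthly abundance proportions of a taxon
#'
#' `p_m = (taxon's pooled abundance in month m, over all habitats and
#' replicates) / (taxon's annual total)`, returned for all 12 months
#' (zeros for months without occurrence). Sums to 1.
#'
#' @param dataset a [CommunityDataset-class].
#' @param taxon taxon label.
#' @param valueMode `"density"` (default) or `"count"`.
#' @return named numeric of length 12.
#' @export
monthlyProportions <- function(dataset, taxon, valueMode = c("density", "count")) {
  stopifnot(methods::is(dataset, "CommunityDataset"))
  valueMode <- match.arg(valueMode)
  if (!taxon %in% dataset@taxa)
    stop(sprintf("taxon '%s' not present in dataset", taxon))
  rec <- dataset@records[dataset@records$taxon == taxon, , drop = FALSE]
  value <- if (valueMode == "density") rec$density else rec$raw_count
  total <- sum(value)
  if (total <= 0) stop(sprintf("taxon '%s' has zero total abundance", taxon))
  p <- vapply(1:12, function(m) sum(value[rec$month == m]), numeric(1)) / total
  stats::setNames(p, 1:12)
}

#' Abundance-weighted environmental occurrence mean
#'
#' `mu = sum_m p_m * env_m`: the mean value of a monthly environmental
#' variable (air temperature, relative humidity) weighted by the taxon's
#' monthly occurrence profile. Bounded by the min and max of `env` over the
#' occupied months.
#'
#' @param p proportion vector (must sum to 1 within 1e-9).
#' @param env monthly environmental values aligned with `p`; must be
#'   non-missing wherever `p > 0`.
#' @return the weighted mean, in the units of `env`.
#' @export
weightedNiche <- function(p, env) {
  if (length(p) != length(env))
    stop("p and env must have equal length")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(p < -1e-12)) stop("proportions must be nonnegative")
  if (any(p > 0 & is.na(env)))
    stop("missing environmental value for an occupied month")
  sum(p[p > 0] * env[p > 0])
}

#' Abundance-weighted niche breadth
#'
#' `sqrt(sum_m p_m * (env_m - mu)^2)`: the population-style weighted SD of
#' the environmental variable over the occurrence profile. Zero iff the
#' occurrence is confined to months sharing a single environmental value.
#'
#' @inheritParams weightedNiche
#' @param mu the weighted mean; computed from `p` and `env` when omitted.
#' @return breadth in the units of `env`, `>= 0`.
#' @export
nicheBreadth <- function(p, env, mu = NULL) {
  if (is.null(mu)) mu <- weightedNiche(p, env)
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  keep <- p > 0
  sqrt(sum(p[keep] * (env[keep] - mu)^2))
}

#' Permutation null test of an occurrence niche
#'
#' Tests the observed weighted mean `mu` against a null in which the taxon
#' is distributed randomly across months. The default null (`"permute"`)
#' permutes the assignment of the monthly abundances to months (preserving
#' the shape of the profile); the alternative (`"multinomial"`)
#' redistributes the individuals multinomially with equal month
#' probabilities. The p-value is two-sided with the add-one correction.
#'
#' @inheritParams weightedNiche
#' @param nIter permutations, default 10000.
#' @param seed optional integer seed.
#' @param nullModel `"permute"` (default) or `"multinomial"`.
#' @param total total abundance used to scale the multinomial null; only
#'   needed for `nullModel = "multinomial"` (default 1000).
#' @return a [NullEnsemble-class] with statistic `"mu"`. A constant `env`
#'   leaves the test undefined: an error is raised.
#' @export
nicheNullTest <- function(p, env, nIter = 10000, seed = NULL,
                          nullModel = c("permute", "multinomial"),
                          total = 1000) {
  nullModel <- match.arg(nullModel)
  if (length(unique(env[!is.na(env)])) < 2)
    stop("environmental values are constant: permutation p undefined")
  observed <- weightedNiche(p, env)
  nMonths <- length(p)
  draws <- .withSeed(seed, {
    if (nullModel == "permute") {
      perm <- replicate(nIter, env[sample.int(nMonths)])
      as.numeric(p %*% perm)
    } else {
      counts <- stats::rmultinom(nIter, size = max(1, round(total)),
                                 prob = rep(1 / nMonths, nMonths))
      as.numeric(crossprod(counts / max(1, round(total)), env))
    }
  })
  methods::new("NullEnsemble",
    statistic = "mu", observed = observed, nullDraws = draws,
    pValue = .permPValue(observed, draws, "two.sided"),
    nIter = nIter, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    alternative = "two.sided")
}

#' Classify a taxon's environmental response
#'
#' Non-significant niches (`p >= alpha`) are `"none"`. Significant niches
#' are `"warmer"`/`"wetter"` when `mu > annualMean + delta`,
#' `"colder"`/`"drier"` when `mu < annualMean - delta`, and `"neutral"`
#' when `mu` lies within `delta` of the annual mean. The half-width
#' `delta` defaults to 0.5 units (deg C; use e.g. 1 for %RH).
#'
#' @param mu the estimated occurrence mean.
#' @param pValue its permutation p-value.
#' @param annualMean annual mean of the environmental variable.
#' @param delta half-width of the "neutral" band, default 0.5.
#' @param alpha significance level, default 0.05.
#' @param variable `"temperature"` (default) or `"humidity"` — selects the
#'   category vocabulary.
#' @return one of `"warmer"`, `"colder"`, `"wetter"`, `"drier"`,
#'   `"neutral"`, `"none"`.
#' @export
classifyNiche <- function(mu, pValue, annualMean, delta = 0.5, alpha = 0.05,
                          variable = c("temperature", "humidity")) {
  variable <- match.arg(variable)
  if (is.na(pValue) || pValue >= alpha) return("none")
  up <- if (variable == "temperature") "warmer" else "wetter"
  down <- if (variable == "temperature") "colder" else "drier"
  if (mu > annualMean + delta) up
  else if (mu < annualMean - delta) down
  else "neutral"
}

#' Estimate occurrence niches for every taxon in a dataset
#'
#' Runs [monthlyProportions()], [weightedNiche()], [nicheBreadth()],
#' [nicheNullTest()] and [classifyNiche()] per taxon for one environmental
#' variable. Taxa observed in fewer than 2 months keep their estimate but
#' are flagged unreliable (`reliable = FALSE`).
#'
#' @param dataset a [CommunityDataset-class].
#' @param env length-12 vector of monthly environmental values.
#' @param variable `"temperature"` or `"humidity"`.
#' @param nIter permutations per taxon, default 10000.
#' @param seed optional integer seed (per-taxon seeds are derived from it).
#' @param delta,alpha classification parameters, see [classifyNiche()].
#' @param valueMode abundance currency for the proportions.
#' @return data.frame with one row per taxon: `taxon`, `variable`, `mu`,
#'   `breadth`, `months_present`, `p_value`, `category`, `reliable`,
#'   `n_iter`, `seed`.
#' @export
estimateNiches <- function(dataset, env, variable = c("temperature", "humidity"),
                           nIter = 10000, seed = NULL, delta = 0.5,
                           alpha = 0.05, valueMode = c("density", "count")) {
  variable <- match.arg(variable)
  valueMode <- match.arg(valueMode)
  stopifnot(methods::is(dataset, "CommunityDataset"))
  if (length(env) != 12) stop("env must hold 12 monthly values")
  annualMean <- mean(env)
  out <- lapply(seq_along(dataset@taxa), function(i) {
    tx <- dataset@taxa[i]
    p <- monthlyProportions(dataset, tx, valueMode = valueMode)
    mu <- weightedNiche(p, env)
    breadth <- nicheBreadth(p, env, mu)
    monthsPresent <- sum(p > 0)
    txSeed <- if (is.null(seed)) NULL else (as.integer(seed) + i) %% .Machine$integer.max
    pv <- nicheNullTest(p, env, nIter = nIter, seed = txSeed)@pValue
    data.frame(
      taxon = tx, variable = variable, mu = mu, breadth = breadth,
      months_present = monthsPresent, p_value = pv,
      category = classifyNiche(mu, pv, annualMean, delta, alpha, variable),
      reliable = monthsPresent >= 2,
      n_iter = nIter,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
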