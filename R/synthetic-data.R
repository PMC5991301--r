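#' @include community-data.R
NULL

#' Configuration for the synthetic community generator
#'
#' Assembles and validates the parameter set of the synthetic survey
#' generator, which emulates a year-long community survey of three forest
#' microhabitats: ~50 taxa with lognormal baseline densities, Dirichlet
#' habitat preferences, Gaussian air-temperature response curves,
#' negative-binomial count noise and lognormal per-sample dry weights,
#' plus a sinusoidal weather year logged hourly by four loggers.
#'
#' @param nTaxa number of taxa, default 50.
#' @param nHabitats number of microhabitats, fixed default 3
#'   (moss, dead_wood, litter).
#' @param nMonths months surveyed, default 12.
#' @param nReplicates replicate samples per microhabitat and month,
#'   default 10.
#' @param tempMean,tempAmplitude annual mean and seasonal amplitude of air
#'   temperature (deg C), defaults 10 and 8 (monthly means ~2..18).
#' @param tempNoiseSd per-reading temperature noise SD (deg C), default 1.
#' @param rhMean,rhSd relative-humidity noise parameters (%), defaults 88
#'   and 12, truncated into `[50, 100]`.
#' @param dirichletConcentration the generalization knob: Dirichlet
#'   concentration of the habitat preferences (small = specialists,
#'   large = generalists), default 1.
#' @param preferenceMode `"dirichlet"` (default) or `"onehot"` (each taxon
#'   bound to a single habitat, cycling through the habitats).
#' @param nbDispersion negative-binomial size (overdispersion) parameter,
#'   default 1.
#' @param baselineMeanlog,baselineSdlog lognormal parameters of the
#'   baseline density (Ind/kg), defaults `log(4000)` and 1.2.
#' @param dryWeightMeanlog,dryWeightSdlog lognormal parameters of the
#'   per-sample dry weight (kg), defaults `log(0.008)` and 0.4.
#' @param flatFraction fraction of taxa with no temperature response,
#'   default 0.3.
#' @param optRange range of temperature optima (deg C), default `c(2, 18)`.
#' @param breadthRange range of response breadths (deg C), default
#'   `c(3, 8)`.
#' @param flatBreadth breadth assigned to non-responding taxa, default
#'   1000 (effectively flat).
#' @param coldSharpening exponent slope sharpening habitat preferences in
#'   cold months (0 = stable preferences; > 0 makes communities more
#'   specialized when cold), default 0.
#' @param turnoverMonth month from which half of the taxa rotate their
#'   habitat preferences (an abrupt community shift), default `NA` (none).
#' @param turnoverFraction fraction of taxa affected by the turnover,
#'   default 2/3 (the fraction at which the rotated taxa's negative
#'   contribution to the consecutive-network correlation exactly cancels
#'   the unchanged taxa's positive one in expectation).
#' @param year calendar year stamped on the weather series, default 2021.
#' @return a validated list of class `"SyntheticConfig"`.
#' @seealso [scenarioConfig()], [generateCommunity()], [generateWeather()]
#' @export
syntheticConfig <- function(nTaxa = 50, nHabitats = 3, nMonths = 12,
                            nReplicates = 10, tempMean = 10,
                            tempAmplitude = 8, tempNoiseSd = 1,
                            rhMean = 88, rhSd = 12,
                            dirichletConcentration = 1,
                            preferenceMode = c("dirichlet", "onehot"),
                            nbDispersion = 1,
                            baselineMeanlog = log(4000), baselineSdlog = 1.2,
                            dryWeightMeanlog = log(0.008),
                            dryWeightSdlog = 0.4,
                            flatFraction = 0.3, optRange = c(2, 18),
                            breadthRange = c(3, 8), flatBreadth = 1000,
                            coldSharpening = 0, turnoverMonth = NA,
                            turnoverFraction = 2 / 3, year = 2021) {
  preferenceMode <- match.arg(preferenceMode)
  cfg <- list(
    nTaxa = as.integer(nTaxa), nHabitats = as.integer(nHabitats),
    nMonths = as.integer(nMonths), nReplicates = as.integer(nReplicates),
    tempMean = tempMean, tempAmplitude = tempAmplitude,
    tempNoiseSd = tempNoiseSd, rhMean = rhMean, rhSd = rhSd,
    dirichletConcentration = dirichletConcentration,
    preferenceMode = preferenceMode, nbDispersion = nbDispersion,
    baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
    dryWeightMeanlog = dryWeightMeanlog, dryWeightSdlog = dryWeightSdlog,
    flatFraction = flatFraction, optRange = optRange,
    breadthRange = breadthRange, flatBreadth = flatBreadth,
    coldSharpening = coldSharpening, turnoverMonth = turnoverMonth,
    turnoverFraction = turnoverFraction, year = as.integer(year)
  )
  stopifnot(cfg$nTaxa >= 1, cfg$nHabitats >= 1, cfg$nMonths >= 1,
            cfg$nReplicates >= 1, cfg$nbDispersion > 0,
            cfg$dirichletConcentration > 0, cfg$tempNoiseSd >= 0,
            cfg$flatFraction >= 0, cfg$flatFraction <= 1)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Preset scenario configurations
#'
#' `"baseline"`: stable habitat preferences all year (every consecutive
#' month pair strongly correlated). `"specialist_shift"`: preferences
#' sharpen in cold months, so node-level specialization d' falls with air
#' temperature. `"may_june_turnover"`: two-thirds of the taxa rotate their
#' habitat preferences from month 6 onward — an abrupt community shift
#' that decorrelates exactly the month 5 -> 6 network pair (at that
#' fraction the rotated taxa's anti-correlated deviations cancel the
#' unchanged taxa's correlated ones in expectation).
#'
#' @param name one of `"baseline"`, `"specialist_shift"`,
#'   `"may_june_turnover"`.
#' @param ... overrides forwarded to [syntheticConfig()].
#' @return a `"SyntheticConfig"`.
#' @export
scenarioConfig <- function(name, ...) {
  presets <- c("baseline", "specialist_shift", "may_june_turnover")
  if (!is.character(name) || length(name) != 1 || !name %in% presets)
    stop(sprintf("unknown scenario '%s'; available presets: %s",
                 as.character(name)[1], paste(presets, collapse = ", ")))
  switch(name,
    baseline = syntheticConfig(...),
    specialist_shift = syntheticConfig(coldSharpening = 2, ...),
    may_june_turnover = syntheticConfig(turnoverMonth = 6, ...)
  )
}

#' Generate a synthetic weather-logger year
#'
#' Hourly readings for 4 loggers from late December of the preceding year
#' through the survey year: air temperature follows a smooth seasonal
#' sinusoid (coldest around New Year, warmest around July) plus Gaussian
#' reading noise; relative humidity is Gaussian noise truncated into
#' `[50, 100]`. Monthly summaries are computed with [aggregateWeather()]
#' over the 5 days preceding the first of each month — exactly how a field
#' survey sampling at the beginning of each month would summarize its
#' loggers — and serve as the ground-truth monthly conditions for
#' [generateCommunity()].
#'
#' @param config a `"SyntheticConfig"`.
#' @param seed optional integer seed.
#' @return list with `series` (weather data.frame) and `summary`
#'   (12-row data.frame from [aggregateWeather()]).
#' @export
generateWeather <- function(config = syntheticConfig(), seed = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  year <- config$year
  start <- as.POSIXct(sprintf("%d-12-26 00:00:00", year - 1), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-12-31 23:00:00", year), tz = "UTC")
  times <- seq(start, end, by = 3600)
  jan1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  doy <- as.numeric(difftime(times, jan1, units = "days"))
  baseTemp <- config$tempMean - config$tempAmplitude * cos(2 * pi * doy / 365)
  nLoggers <- 4
  series <- .withSeed(seed, {
    do.call(rbind, lapply(seq_len(nLoggers), function(l) {
      data.frame(
        timestamp = times,
        logger_id = sprintf("logger_%d", l),
        temp_c = baseTemp + stats::rnorm(length(times), 0, config$tempNoiseSd),
        rh_pct = pmin(100, pmax(50, stats::rnorm(length(times), config$rhMean,
                                                 config$rhSd)))
      )
    }))
  })
  series <- series[order(series$logger_id, series$timestamp), ]
  rownames(series) <- NULL
  summary <- do.call(rbind, lapply(seq_len(config$nMonths), function(m) {
    aggregateWeather(series, as.Date(sprintf("%d-%02d-01", year, m)))
  }))
  list(series = series, summary = summary)
}

# month-dependent preference matrix for one taxon under the scenario knobs
.monthPreference <- function(pref, month, theta, config, rotated) {
  p <- pref
  if (rotated && !is.na(config$turnoverMonth) && month >= config$turnoverMonth)
    p <- p[c(seq_along(p)[-1], 1)]
  if (config$coldSharpening > 0) {
    rng <- max(theta) - min(theta)
    e <- 1 + config$coldSharpening * (max(theta) - theta[month]) / max(rng, 1e-9)
    p <- p^e
    p <- p / sum(p)
  }
  p
}

#' Generate a synthetic community survey with known ground truth
#'
#' Expected count for (taxon, habitat, month, replicate) =
#' `baseline * habitatPreference[habitat] *
#' exp(-(theta_m - optimum)^2 / (2 * breadth^2)) * dryWeight`,
#' with counts drawn negative-binomially, dry weights drawn lognormally
#' per sample (shared by all taxa in the sample), and the monthly
#' temperatures `theta_m` taken from the generated weather summaries.
#' Scenario knobs (`coldSharpening`, `turnoverMonth`) modulate the
#' preferences per month; the returned truth table records every taxon's
#' generating parameters and response class.
#'
#' @param config a `"SyntheticConfig"`.
#' @param seed optional integer seed (weather and community sub-streams
#'   are derived from it deterministically).
#' @return list with `dataset` (a [CommunityDataset-class]), `truth`
#'   (data.frame of species profiles), `weather` (as from
#'   [generateWeather()]) and `config`.
#' @export
generateCommunity <- function(config = syntheticConfig(), seed = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  weatherSeed <- if (is.null(seed)) NULL else (as.integer(seed) * 2L + 1L) %% 2147483647L
  commSeed <- if (is.null(seed)) NULL else (as.integer(seed) * 2L + 2L) %% 2147483647L
  weather <- generateWeather(config, seed = weatherSeed)
  theta <- weather$summary$theta_m
  nT <- config$nTaxa; nH <- config$nHabitats
  nM <- config$nMonths; nR <- config$nReplicates
  habitatNames <- if (nH == 3) c("moss", "dead_wood", "litter") else
    sprintf("habitat_%02d", seq_len(nH))
  taxonNames <- sprintf("taxon_%02d", seq_len(nT))

  out <- .withSeed(commSeed, {
    baseline <- stats::rlnorm(nT, config$baselineMeanlog, config$baselineSdlog)
    pref <- switch(config$preferenceMode,
      dirichlet = {
        g <- matrix(stats::rgamma(nT * nH, shape = config$dirichletConcentration),
                    nrow = nT)
        g / rowSums(g)
      },
      onehot = {
        p <- matrix(0, nT, nH)
        p[cbind(seq_len(nT), ((seq_len(nT) - 1) %% nH) + 1)] <- 1
        p
      })
    flat <- stats::runif(nT) < config$flatFraction
    optimum <- stats::runif(nT, config$optRange[1], config$optRange[2])
    breadth <- stats::runif(nT, config$breadthRange[1], config$breadthRange[2])
    breadth[flat] <- config$flatBreadth
    rotated <- seq_len(nT) <= round(config$turnoverFraction * nT)
    annual <- mean(theta)
    respClass <- ifelse(flat, "none",
                 ifelse(optimum > annual + 0.5, "warmer",
                 ifelse(optimum < annual - 0.5, "colder", "neutral")))

    dw <- array(stats::rlnorm(nH * nM * nR, config$dryWeightMeanlog,
                              config$dryWeightSdlog), dim = c(nH, nM, nR))
    grid <- expand.grid(taxon = seq_len(nT), habitat = seq_len(nH),
                        month = seq_len(nM), replicate = seq_len(nR))
    tempFactor <- exp(-(outer(theta, optimum, "-"))^2 /
                      (2 * matrix(breadth^2, nM, nT, byrow = TRUE)))
    prefEff <- array(0, dim = c(nT, nH, nM))
    for (i in seq_len(nT)) for (m in seq_len(nM))
      prefEff[i, , m] <- .monthPreference(pref[i, ], m, theta, config, rotated[i])
    lambda <- baseline[grid$taxon] *
      prefEff[cbind(grid$taxon, grid$habitat, grid$month)] *
      tempFactor[cbind(grid$month, grid$taxon)] *
      dw[cbind(grid$habitat, grid$month, grid$replicate)]
    counts <- stats::rnbinom(nrow(grid), mu = lambda, size = config$nbDispersion)
    list(baseline = baseline, pref = pref, flat = flat, optimum = optimum,
         breadth = breadth, rotated = rotated, respClass = respClass,
         dw = dw, grid = grid, counts = counts)
  })

  rec <- data.frame(
    taxon = taxonNames[out$grid$taxon],
    microhabitat = habitatNames[out$grid$habitat],
    month = out$grid$month,
    replicate = out$grid$replicate,
    raw_count = out$counts,
    dry_weight_kg = out$dw[cbind(out$grid$habitat, out$grid$month,
                                 out$grid$replicate)],
    stringsAsFactors = FALSE
  )
  dataset <- communityDataset(rec)

  truth <- data.frame(
    taxon = taxonNames,
    baseline_abundance = out$baseline,
    out$pref,
    temp_optimum = ifelse(out$flat, NA_real_, out$optimum),
    temp_breadth = out$breadth,
    flat_response = out$flat,
    rotated = out$rotated,
    response_class = out$respClass,
    stringsAsFactors = FALSE
  )
  names(truth)[3:(2 + config$nHabitats)] <- paste0("pref_", habitatNames)

  list(dataset = dataset, truth = truth, weather = weather, config = config)
}

#' Write a synthetic survey to the CSV schemas the readers consume
#'
#' @param sim result of [generateCommunity()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the paths written (`survey`,
#'   `weather`, `truth`).
#' @export
writeSyntheticSurvey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surveyPath <- file.path(dir, "survey.csv")
  weatherPath <- file.path(dir, "weather.csv")
  truthPath <- file.path(dir, "truth.csv")
  rec <- records(sim$dataset)
  utils::write.csv(rec[, c("taxon", "microhabitat", "month", "replicate",
                           "raw_count", "dry_weight_kg")],
                   surveyPath, row.names = FALSE)
  ws <- sim$weather$series
  ws$timestamp <- format(ws$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(ws, weatherPath, row.names = FALSE)
  utils::write.csv(sim$truth, truthPath, row.names = FALSE)
  invisible(c(survey = surveyPath, weather = weatherPath, truth = truthPath))
}
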