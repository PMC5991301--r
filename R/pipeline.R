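#' @include fixtures.R
NULL

.defaultPipelineConfig <- function() {
  list(
    nullIters = 10000,    # randomized networks per monthly H2' null test
    pairwisePerms = 1000, # permutations per pairwise H2' test
    mantelPerms = 1000,   # permutations per consecutive-month correlation
    nicheIters = 10000,   # permutations per occurrence-niche test
    alpha = 0.05,
    mode = "continuous",  # extremum heuristics for index values
    ltMethod = "relative",
    deltaTemp = 0.5,      # neutral band half-width, deg C
    deltaRH = 1,          # neutral band half-width, %RH
    windowDays = 5,
    samplingYear = NA,    # year of the sampling dates; NA = infer from weather
    seed = NA
  )
}

.loadPipelineConfig <- function(config) {
  base <- .defaultPipelineConfig()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0)
    stop(sprintf("unknown config option(s): %s", paste(unknown, collapse = ", ")))
  utils::modifyList(base, config)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[microspec] stage %-22s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full seasonal specialization analysis
#'
#' Executes the whole pipeline on a survey and a weather input:
#' abundance standardization, monthly and pooled interaction matrices,
#' diversity summaries, H2'/d' with fixed-margin null tests per month and
#' pooled, pairwise H2' distances with permutation tests, link-temperature
#' correlations of consecutive months, occurrence-niche estimation and
#' classification for temperature and humidity, and the monthly
#' association statistics (H2' ~ temperature and ~ humidity OLS, Wilks
#' MANOVA of d' on temperature with protected univariate follow-ups,
#' temperature ~ humidity rank correlation, d' ~ pairwise-distance
#' product-moment correlation).
#'
#' @param survey a [CommunityDataset-class], or a path to a survey CSV
#'   ([readSurveyTable()] schema).
#' @param weather either a monthly summary data.frame with columns `month`,
#'   `theta_m` (or `temp_mean`) and `rh_m` (or `rh_mean`), or a path to a
#'   weather-logger CSV ([readWeatherSeries()] schema) to be aggregated
#'   over the `windowDays` preceding the first of each month.
#' @param config named list of options or a YAML file path; see
#'   Details. Unset options take the package defaults (10000 network-null
#'   iterations, 1000 Mantel permutations, 10000 niche iterations,
#'   alpha = 0.05).
#' @param outDir optional directory; when given, every report table is
#'   written as CSV plus a JSON run-metadata file.
#' @return a list of class `"AnalysisReport"`: `diversity`,
#'   `specialization` (monthly + pooled H2'/d' rows), `nullTests`,
#'   `pairwise`, `dynamics`, `nicheTemperature`, `nicheHumidity`,
#'   `associations`, `weather`, `meta`.
#' @export
runFullAnalysis <- function(survey, weather, config = NULL, outDir = NULL) {
  cfg <- .loadPipelineConfig(config)
  seed <- if (is.na(cfg$seed)) NULL else as.integer(cfg$seed)

  dataset <- .stage("read_survey", {
    if (methods::is(survey, "CommunityDataset")) survey
    else readSurveyTable(survey)
  })

  weatherSummary <- .stage("aggregate_weather", {
    if (is.data.frame(weather) && !("timestamp" %in% names(weather))) {
      w <- weather
      if ("temp_mean" %in% names(w) && !"theta_m" %in% names(w))
        w$theta_m <- w$temp_mean
      if ("rh_mean" %in% names(w) && !"rh_m" %in% names(w))
        w$rh_m <- w$rh_mean
      stopifnot(all(c("month", "theta_m", "rh_m") %in% names(w)))
      w
    } else {
      series <- if (is.character(weather)) readWeatherSeries(weather)
                else validateWeatherSeries(weather)
      yr <- if (is.na(cfg$samplingYear))
        as.integer(format(max(series$timestamp), "%Y")) else
        as.integer(cfg$samplingYear)
      do.call(rbind, lapply(sort(dataset@months), function(m)
        aggregateWeather(series, as.Date(sprintf("%d-%02d-01", yr, m)),
                         cfg$windowDays)))
    }
  })
  months <- sort(dataset@months)
  thetaByMonth <- weatherSummary$theta_m[match(1:12, weatherSummary$month)]
  rhByMonth <- weatherSummary$rh_m[match(1:12, weatherSummary$month)]

  diversity <- .stage("diversity", summarizeByGroup(dataset))

  nets <- .stage("build_networks", {
    lapply(stats::setNames(months, paste0("m", months)), function(m)
      buildInteractionMatrix(dataset, months = m, valueMode = "density"))
  })
  pooled <- buildInteractionMatrix(dataset, valueMode = "density")

  specialization <- .stage("specialization", {
    rows <- lapply(c(as.list(months), list("pooled")), function(m) {
      net <- if (identical(m, "pooled")) pooled else nets[[paste0("m", m)]]
      sp <- h2Prime(net, mode = cfg$mode)
      dps <- lapply(habitats(net), function(h) dPrime(net, h, mode = cfg$mode))
      data.frame(
        month = as.character(m),
        h2 = sp@h2, h2_min = sp@h2Min, h2_max = sp@h2Max,
        h2_prime = sp@h2Prime,
        stats::setNames(as.list(vapply(dps, function(d) d@dPrime, numeric(1))),
                        paste0("dprime_", habitats(net))),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    })
    do.call(rbind, rows)
  })

  nullTests <- .stage("null_tests", {
    do.call(rbind, lapply(seq_along(months), function(k) {
      m <- months[k]
      cnt <- buildInteractionMatrix(dataset, months = m, valueMode = "count")
      s <- if (is.null(seed)) NULL else (seed + 100L + k) %% 2147483647L
      nt <- nullTestH2(cnt, nIter = cfg$nullIters, seed = s, mode = cfg$mode)
      data.frame(month = m, observed_h2_prime = nt@observed,
                 null_mean = mean(nt@nullDraws), null_sd = stats::sd(nt@nullDraws),
                 p_value = nt@pValue, n_iter = cfg$nullIters,
                 seed = if (is.null(s)) NA_integer_ else s)
    }))
  })

  pairwise <- .stage("pairwise_h2", {
    habs <- habitats(pooled)
    pairs <- utils::combn(habs, 2, simplify = FALSE)
    do.call(rbind, lapply(seq_along(months), function(k) {
      m <- months[k]
      net <- nets[[paste0("m", m)]]
      cnt <- buildInteractionMatrix(dataset, months = m, valueMode = "count")
      do.call(rbind, lapply(seq_along(pairs), function(j) {
        pr <- pairs[[j]]
        dist <- pairwiseH2Distance(net, pr, mode = cfg$mode)
        s <- if (is.null(seed)) NULL else (seed + 200L + 10L * k + j) %% 2147483647L
        tst <- pairwiseH2Test(cnt, pr, nIter = cfg$pairwisePerms, seed = s,
                              mode = cfg$mode)
        data.frame(month = m, habitat_a = pr[1], habitat_b = pr[2],
                   h2_distance = dist, p_value = tst@pValue,
                   n_perm = cfg$pairwisePerms,
                   seed = if (is.null(s)) NA_integer_ else s,
                   stringsAsFactors = FALSE)
      }))
    }))
  })

  dynamics <- .stage("consecutive_networks", {
    if (length(months) < 2) NULL else
    do.call(rbind, lapply(seq_len(length(months) - 1), function(k) {
      mA <- months[k]; mB <- months[k + 1]
      cntA <- buildInteractionMatrix(dataset, months = mA, valueMode = "count")
      cntB <- buildInteractionMatrix(dataset, months = mB, valueMode = "count")
      s <- if (is.null(seed)) NULL else (seed + 300L + k) %% 2147483647L
      nc <- consecutiveCorrelation(cntA, cntB, nPerm = cfg$mantelPerms,
                                   seed = s, method = cfg$ltMethod,
                                   monthPair = c(mA, mB))
      data.frame(month_a = mA, month_b = mB, r = nc@rObs, r_mean = nc@rMean,
                 r_sd = nc@rSd, p_value = nc@pValue, n_perm = cfg$mantelPerms,
                 n_shared_taxa = nc@nShared, method = cfg$ltMethod,
                 seed = if (is.null(s)) NA_integer_ else s,
                 stringsAsFactors = FALSE)
    }))
  })

  nicheTemperature <- .stage("niche_temperature",
    estimateNiches(dataset, thetaByMonth, "temperature",
                   nIter = cfg$nicheIters,
                   seed = if (is.null(seed)) NULL else seed + 400L,
                   delta = cfg$deltaTemp, alpha = cfg$alpha))
  nicheHumidity <- .stage("niche_humidity",
    estimateNiches(dataset, rhByMonth, "humidity",
                   nIter = cfg$nicheIters,
                   seed = if (is.null(seed)) NULL else seed + 500L,
                   delta = cfg$deltaRH, alpha = cfg$alpha))

  associations <- .stage("associations", {
    monthly <- specialization[specialization$month != "pooled", ]
    mIdx <- match(as.integer(monthly$month), weatherSummary$month)
    temp <- weatherSummary$theta_m[mIdx]
    rh <- weatherSummary$rh_m[mIdx]
    dpCols <- grep("^dprime_", names(monthly), value = TRUE)
    rows <- list()
    o <- olsFTest(temp, monthly$h2_prime)
    rows[["h2_vs_temp"]] <- data.frame(test = "ols_h2_prime_temperature",
      statistic = o$f_stat, df1 = o$df[1], df2 = o$df[2], p_value = o$p_value)
    o <- olsFTest(rh, monthly$h2_prime)
    rows[["h2_vs_rh"]] <- data.frame(test = "ols_h2_prime_humidity",
      statistic = o$f_stat, df1 = o$df[1], df2 = o$df[2], p_value = o$p_value)
    wm <- wilksManova(as.matrix(monthly[, dpCols]), temp)
    rows[["manova"]] <- data.frame(test = "wilks_manova_dprime_temperature",
      statistic = wm$wilks_lambda, df1 = wm$df[1], df2 = wm$df[2],
      p_value = wm$p_value)
    protected <- wm$p_value < cfg$alpha
    for (cn in dpCols) {
      o <- olsFTest(temp, monthly[[cn]])
      rows[[cn]] <- data.frame(
        test = sprintf("protected_anova_%s_temperature%s", cn,
                       if (protected) "" else "_unprotected"),
        statistic = o$f_stat, df1 = o$df[1], df2 = o$df[2], p_value = o$p_value)
    }
    rc <- rankCorrelation(temp, rh)
    rows[["temp_rh"]] <- data.frame(test = "spearman_temperature_humidity",
      statistic = rc$rho, df1 = NA, df2 = NA, p_value = rc$p_value)
    # d' of each habitat against the mean pairwise distance involving it
    habs <- sub("^dprime_", "", dpCols)
    dVals <- unlist(monthly[, dpCols], use.names = FALSE)
    pwMean <- unlist(lapply(habs, function(h) {
      vapply(as.integer(monthly$month), function(m) {
        sel <- pairwise$month == m & (pairwise$habitat_a == h | pairwise$habitat_b == h)
        mean(pairwise$h2_distance[sel])
      }, numeric(1))
    }))
    pc <- pearsonCorrelation(dVals, pwMean)
    rows[["d_vs_pairwise"]] <- data.frame(test = "pearson_dprime_pairwise_distance",
      statistic = pc$r, df1 = NA, df2 = NA, p_value = pc$p_value)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  report <- list(
    diversity = diversity, specialization = specialization,
    nullTests = nullTests, pairwise = pairwise, dynamics = dynamics,
    nicheTemperature = nicheTemperature, nicheHumidity = nicheHumidity,
    associations = associations, weather = weatherSummary,
    meta = list(
      package_version = as.character(utils::packageVersion("microspec")),
      config = cfg,
      n_taxa = length(dataset@taxa),
      n_records = nrow(dataset@records),
      timestamp = NA  # deliberately unset: reports must be reproducible
    )
  )
  class(report) <- "AnalysisReport"

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("diversity", "specialization", "nullTests", "pairwise",
                 "dynamics", "nicheTemperature", "nicheHumidity",
                 "associations", "weather")) {
      if (!is.null(report[[nm]]))
        utils::write.csv(report[[nm]], file.path(outDir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(report$meta, file.path(outDir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport\n")
  cat(sprintf("  taxa: %d, records: %d\n", x$meta$n_taxa, x$meta$n_records))
  pooledRow <- x$specialization[x$specialization$month == "pooled", ]
  cat(sprintf("  pooled H2' = %.3f\n", pooledRow$h2_prime))
  dpCols <- grep("^dprime_", names(pooledRow), value = TRUE)
  for (cn in dpCols)
    cat(sprintf("  pooled %s = %.3f\n", cn, pooledRow[[cn]]))
  invisible(x)
}
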