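#' @include utils.R
NULL

#' Standardize an individual count by sample dry weight
#'
#' Converts a raw individual count into a density in individuals per kg of
#' sample dry weight (Ind/kg), the unit that makes samples of different
#' physical size comparable across microhabitats and months.
#'
#' @param rawCount integer count of individuals, `>= 0`.
#' @param dryWeightKg sample dry weight in kilograms, `> 0`.
#' @return density in Ind/kg dry weight.
#' @examples
#' standardizeAbundance(50, 0.1)   # 500 Ind/kg
#' @export
standardizeAbundance <- function(rawCount, dryWeightKg) {
  if (any(rawCount < 0)) stop("rawCount must be >= 0")
  if (any(dryWeightKg <= 0)) stop("dryWeightKg must be > 0")
  rawCount / dryWeightKg
}

#' Construct a CommunityDataset from a long-format data.frame
#'
#' Validates a long sample table (one row per taxon x microhabitat x month x
#' replicate), computes densities, and returns a [CommunityDataset-class].
#'
#' @param df data.frame with columns `taxon`, `microhabitat`, `month`,
#'   `replicate`, `raw_count`, `dry_weight_kg`.
#' @return a validated [CommunityDataset-class].
#' @export
communityDataset <- function(df) {
  req <- c("taxon", "microhabitat", "month", "replicate", "raw_count",
           "dry_weight_kg")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop(sprintf("survey table is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- which(df$raw_count < 0)
  if (length(bad) > 0)
    stop(sprintf("negative raw_count in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(df$dry_weight_kg <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive dry_weight_kg in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  key <- paste(df$taxon, df$microhabitat, df$month, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop(sprintf("duplicated (taxon, microhabitat, month, replicate) key in row(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  rec <- data.frame(
    taxon = as.character(df$taxon),
    microhabitat = as.character(df$microhabitat),
    month = as.integer(df$month),
    replicate = as.integer(df$replicate),
    raw_count = as.numeric(df$raw_count),
    dry_weight_kg = as.numeric(df$dry_weight_kg),
    stringsAsFactors = FALSE
  )
  rec$density <- standardizeAbundance(rec$raw_count, rec$dry_weight_kg)
  methods::new("CommunityDataset",
    records = rec,
    taxa = sort(unique(rec$taxon)),
    habitats = sort(unique(rec$microhabitat)),
    months = sort(unique(rec$month))
  )
}

#' Read a long-format community survey table
#'
#' Reads a delimiter-separated survey file (UTF-8, `.` decimal separator)
#' with a header and returns a validated [CommunityDataset-class]. Column
#' names can be remapped via `dialect`, a named character vector mapping the
#' canonical names (`taxon`, `microhabitat`, `month`, `replicate`,
#' `raw_count`, `dry_weight_kg`) to the names used in the file.
#'
#' @param path path to a CSV file.
#' @param dialect optional named character vector, e.g.
#'   `c(taxon = "species", dry_weight_kg = "dw")`.
#' @param sep field separator, default `","`.
#' @return a [CommunityDataset-class].
#' @export
readSurveyTable <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("survey file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      src <- dialect[[canonical]]
      if (!src %in% names(df))
        stop(sprintf("dialect maps '%s' to missing column '%s'", canonical, src))
      names(df)[names(df) == src] <- canonical
    }
  }
  communityDataset(df)
}

#' Read a weather-logger series
#'
#' Reads a logger CSV with columns `timestamp` (ISO-8601), `logger_id`,
#' `temp_c`, `rh_pct`. Relative humidity must lie in `[0, 100]`; timestamps
#' must be strictly increasing within each logger.
#'
#' @param path path to a CSV file.
#' @param tz timezone for timestamp parsing, default `"UTC"`.
#' @return data.frame with parsed `timestamp` (POSIXct), `logger_id`,
#'   `temp_c`, `rh_pct`.
#' @export
readWeatherSeries <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("weather file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("timestamp", "logger_id", "temp_c", "rh_pct")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop(sprintf("weather table is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamp(s) in weather table")
  df$timestamp <- ts
  validateWeatherSeries(df)
}

#' Validate a weather series data.frame
#'
#' @param df data.frame with `timestamp` (POSIXct), `logger_id`, `temp_c`,
#'   `rh_pct`.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validateWeatherSeries <- function(df) {
  if (any(df$rh_pct < 0 | df$rh_pct > 100))
    stop("relative humidity outside [0, 100] in weather series")
  for (id in unique(df$logger_id)) {
    ts <- df$timestamp[df$logger_id == id]
    if (any(diff(as.numeric(ts)) <= 0))
      stop(sprintf("timestamps not strictly increasing for logger '%s'", id))
  }
  df
}

#' Aggregate weather readings over the window preceding a sampling date
#'
#' Pools the readings of all loggers inside the half-open window
#' `[samplingDate - windowDays, samplingDate)` — every logger's readings
#' weighted equally — and returns the mean and SD of temperature and
#' relative humidity. The sampling instant itself is excluded, so a reading
#' taken exactly at the sampling date never enters the summary.
#'
#' @param series weather data.frame as returned by [readWeatherSeries()].
#' @param samplingDate a `Date` (or coercible string).
#' @param windowDays length of the window in days, default 5.
#' @return one-row data.frame: `month`, `theta_m` (mean temp, deg C),
#'   `theta_sd`, `rh_m` (mean RH, %), `rh_sd`, `n_readings`.
#' @export
aggregateWeather <- function(series, samplingDate, windowDays = 5) {
  samplingDate <- as.Date(samplingDate)
  t1 <- as.POSIXct(paste(samplingDate, "00:00:00"), tz = "UTC")
  t0 <- t1 - windowDays * 86400
  inWindow <- series$timestamp >= t0 & series$timestamp < t1
  if (!any(inWindow))
    stop(sprintf("no weather readings in the %d-day window before %s (month %d)",
                 windowDays, format(samplingDate),
                 as.integer(format(samplingDate, "%m"))))
  w <- series[inWindow, , drop = FALSE]
  data.frame(
    month = as.integer(format(samplingDate, "%m")),
    theta_m = mean(w$temp_c),
    theta_sd = stats::sd(w$temp_c),
    rh_m = mean(w$rh_pct),
    rh_sd = stats::sd(w$rh_pct),
    n_readings = nrow(w)
  )
}

#' Construct an InteractionMatrix from a weighted matrix
#'
#' Low-level constructor: wraps a nonnegative taxon-by-habitat matrix
#' (rownames = taxa, colnames = habitats) into an
#' [InteractionMatrix-class], dropping all-zero taxon rows.
#'
#' @param values numeric matrix with dimnames.
#' @param valueMode `"density"` (default) or `"count"`.
#' @return an [InteractionMatrix-class].
#' @export
interactionMatrix <- function(values, valueMode = c("density", "count")) {
  valueMode <- match.arg(valueMode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("taxon_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("habitat_", seq_len(ncol(values)))
  keep <- rowSums(values) > 0
  if (!any(keep)) stop("interaction matrix is all zero")
  values <- values[keep, , drop = FALSE]
  methods::new("InteractionMatrix",
    values = values,
    rowTotals = stats::setNames(rowSums(values), rownames(values)),
    colTotals = stats::setNames(colSums(values), colnames(values)),
    grandTotal = sum(values),
    valueMode = valueMode
  )
}

#' Build the taxon-by-microhabitat interaction matrix of a dataset
#'
#' Sums the chosen value (density in Ind/kg, or raw counts) over the
#' selected months and all replicates per (taxon, microhabitat) cell.
#' Taxa that are absent from the selection are dropped, so the matrix only
#' carries observed taxa (entropy terms are undefined for empty rows).
#'
#' @param dataset a [CommunityDataset-class].
#' @param months integer vector of months to pool; `NULL` (default) pools
#'   all months present.
#' @param valueMode `"density"` (default) or `"count"`.
#' @return an [InteractionMatrix-class].
#' @export
buildInteractionMatrix <- function(dataset, months = NULL,
                                   valueMode = c("density", "count")) {
  stopifnot(methods::is(dataset, "CommunityDataset"))
  valueMode <- match.arg(valueMode)
  if (is.null(months)) months <- dataset@months
  months <- as.integer(months)
  if (length(months) == 0) stop("empty month selection")
  missing_m <- setdiff(months, dataset@months)
  if (length(missing_m) > 0)
    stop(sprintf("month(s) not present in dataset: %s",
                 paste(missing_m, collapse = ", ")))
  rec <- dataset@records
  rec <- rec[rec$month %in% months, , drop = FALSE]
  value <- if (valueMode == "density") rec$density else rec$raw_count
  agg <- tapply(value,
                list(factor(rec$taxon, levels = dataset@taxa),
                     factor(rec$microhabitat, levels = dataset@habitats)),
                sum, default = 0)
  mat <- matrix(agg, nrow = length(dataset@taxa),
                dimnames = list(dataset@taxa, dataset@habitats))
  if (sum(mat) <= 0) stop("selected months contain no individuals")
  interactionMatrix(mat, valueMode = valueMode)
}

#' Export an interaction matrix as CSV with a JSON margin sidecar
#'
#' @param matrix an [InteractionMatrix-class].
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return invisibly, the two paths written.
#' @export
exportInteractionMatrix <- function(matrix, path) {
  stopifnot(methods::is(matrix, "InteractionMatrix"))
  df <- data.frame(taxon = rownames(matrix@values), matrix@values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(row_totals = as.list(matrix@rowTotals),
         col_totals = as.list(matrix@colTotals),
         grand_total = matrix@grandTotal,
         value_mode = matrix@valueMode),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
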