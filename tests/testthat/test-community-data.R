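test_that("abundance standardization divides counts by dry weight", {
  expect_equal(standardizeAbundance(50, 0.1), 500)
  expect_equal(standardizeAbundance(0, 0.3), 0)
  expect_equal(standardizeAbundance(7, 0.035), 200)
  # scale consistency: doubling count and weight jointly changes nothing
  for (k in c(2, 5, 10))
    expect_equal(standardizeAbundance(k * 7, k * 0.035),
                 standardizeAbundance(7, 0.035))
  expect_error(standardizeAbundance(5, 0), "dryWeightKg")
  expect_error(standardizeAbundance(-1, 0.1), "rawCount")
})

test_that("survey tables are validated and densities derived", {
  df <- make_survey(
    list("a", "moss", 1, 1, 10, 0.1),
    list("b", "moss", 1, 1, 0, 0.2),
    list("c", "litter", 2, 1, 5, 0.05))
  ds <- communityDataset(df)
  expect_s4_class(ds, "CommunityDataset")
  expect_equal(records(ds)$density, c(100, 0, 100))
  expect_equal(taxa(ds), c("a", "b", "c"))
  expect_equal(surveyMonths(ds), c(1L, 2L))

  dup <- rbind(df, df[1, ])
  expect_error(communityDataset(dup), "duplicated")
  neg <- df; neg$raw_count[2] <- -1
  expect_error(communityDataset(neg), "negative raw_count in row\\(s\\): 2")
  zw <- df; zw$dry_weight_kg[3] <- 0
  expect_error(communityDataset(zw), "row\\(s\\): 3")
  expect_error(communityDataset(df[, -1]), "taxon")
})

test_that("survey reader maps dialect columns and reports schema errors", {
  df <- make_survey(list("a", "moss", 1, 1, 10, 0.1),
                    list("a", "litter", 1, 1, 4, 0.2))
  names(df)[names(df) == "taxon"] <- "species"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ds <- readSurveyTable(path, dialect = c(taxon = "species"))
  expect_equal(sort(records(ds)$density), c(20, 100))
  expect_error(readSurveyTable(path), "taxon")
  expect_error(readSurveyTable("no/such/file.csv"), "not found")
})

test_that("packaged pooled survey matches its published group totals", {
  df <- oribatidPooledAbundance()
  expect_equal(nrow(df), 61)
  enarthronota <- c("Brachychthoniidae spp.", "Cosmochthonius lanatus",
                    "Eniochthonius minutissimus", "Hypochthonius rufulus")
  expect_equal(sum(df$moss[df$taxon %in% enarthronota]), 624686)
  nothrina <- c("Camisia spinifer", "Nanhermannia nana", "Nothrus palustris",
                "Nothrus silvestris", "Platynothrus peltifer")
  expect_equal(sum(df$litter[df$taxon %in% nothrina]), 130344)
  net <- oribatidPooledNetwork()
  expect_s4_class(net, "InteractionMatrix")
  expect_equal(unname(colTotals(net)), unname(colSums(
    as.matrix(df[, c("moss", "dead_wood", "litter")]))))
})

test_that("interaction matrices aggregate additively and drop empty taxa", {
  ds <- communityDataset(make_survey(list("taxA", "moss", 1, 1, 1, 0.01)))
  m1 <- buildInteractionMatrix(ds)
  expect_equal(dim(interactionValues(m1)), c(1, 1))
  expect_equal(grandTotal(m1), 100)

  ds2 <- communityDataset(make_survey(
    list("taxA", "moss", 1, 1, 5, 0.1),
    list("taxA", "moss", 2, 1, 10, 0.2)))
  m2 <- buildInteractionMatrix(ds2)
  expect_equal(unname(interactionValues(m2)[1, 1]), 100)

  # additivity: the matrix of a month partition sums to the pooled matrix
  set.seed(1)
  sim <- generateCommunity(syntheticConfig(nTaxa = 8, nReplicates = 2), seed = 42)
  pooled <- buildInteractionMatrix(sim$dataset)
  parts <- lapply(list(1:4, 5:8, 9:12), function(ms)
    buildInteractionMatrix(sim$dataset, months = ms))
  summed <- Reduce(`+`, lapply(parts, function(p) {
    full <- matrix(0, length(taxa(pooled)), 3,
                   dimnames = list(taxa(pooled), habitats(pooled)))
    full[taxa(p), habitats(p)] <- interactionValues(p)
    full
  }))
  expect_equal(summed, interactionValues(pooled))

  # zero-abundance taxa are dropped
  dsz <- communityDataset(make_survey(
    list("a", "moss", 1, 1, 10, 0.1),
    list("b", "moss", 1, 1, 0, 0.1)))
  expect_equal(taxa(buildInteractionMatrix(dsz)), "a")

  expect_error(buildInteractionMatrix(sim$dataset, months = integer(0)), "empty")
  expect_error(buildInteractionMatrix(sim$dataset, months = 13), "not present")
  expect_no_error(buildInteractionMatrix(dsz, months = 1, valueMode = "count"))
})

test_that("count mode sums raw counts, not densities", {
  ds <- communityDataset(make_survey(
    list("a", "moss", 1, 1, 10, 0.1),
    list("a", "moss", 1, 2, 20, 0.5)))
  cnt <- buildInteractionMatrix(ds, valueMode = "count")
  expect_equal(unname(interactionValues(cnt)[1, 1]), 30)
  den <- buildInteractionMatrix(ds, valueMode = "density")
  expect_equal(unname(interactionValues(den)[1, 1]), 140)
})

test_that("weather aggregation pools loggers over a half-open window", {
  series <- make_constant_weather("2021-02-01", temp = 10, rh = 80)
  w <- aggregateWeather(series, "2021-02-01")
  expect_equal(w$theta_m, 10)
  expect_equal(w$theta_sd, 0)
  expect_equal(w$rh_m, 80)
  expect_equal(w$rh_sd, 0)
  expect_equal(w$month, 2L)

  # a reading exactly at the sampling instant is excluded
  atDate <- data.frame(
    timestamp = as.POSIXct("2021-02-01 00:00:00", tz = "UTC"),
    logger_id = "L1", temp_c = 99, rh_pct = 10)
  w2 <- aggregateWeather(rbind(series, atDate), "2021-02-01")
  expect_equal(w2, w)

  # permutation invariance to reading order and logger labels
  shuffled <- series[sample.int(nrow(series)), ]
  shuffled$logger_id <- rev(shuffled$logger_id)
  expect_equal(aggregateWeather(shuffled, "2021-02-01"), w)

  expect_error(aggregateWeather(series, "2021-03-15"), "month 3")
})

test_that("a synthetic winter window reproduces its target summary", {
  # build readings whose sample mean/SD equal the January target exactly
  t1 <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  times <- seq(t1 - 5 * 86400, t1 - 3600, by = 3600)
  set.seed(99)
  z <- as.numeric(scale(rnorm(length(times))))
  series <- data.frame(timestamp = times, logger_id = "L1",
                       temp_c = 2.1 + 1.4 * z,
                       rh_pct = pmin(100, pmax(0, 79 + 16 * z)))
  w <- aggregateWeather(series, "2021-01-01")
  expect_equal(w$theta_m, 2.1, tolerance = 1e-12)
  expect_equal(w$theta_sd, 1.4, tolerance = 1e-12)
  expect_equal(w$rh_m, 79, tolerance = 0.2)   # truncation at 100 nudges RH
  expect_equal(w$rh_sd, 16, tolerance = 0.5)
})

test_that("weather reader rejects bad humidity and disordered timestamps", {
  series <- make_constant_weather("2021-02-01")
  path <- withr::local_tempfile(fileext = ".csv")
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(out, path, row.names = FALSE)
  rd <- readWeatherSeries(path)
  expect_equal(nrow(rd), nrow(series))

  bad <- out; bad$rh_pct[5] <- 105
  write.csv(bad, path, row.names = FALSE)
  expect_error(readWeatherSeries(path), "humidity")

  dis <- out[c(2, 1, 3:nrow(out)), ]
  write.csv(dis, path, row.names = FALSE)
  expect_error(readWeatherSeries(path), "strictly increasing")
})

test_that("matrix export writes values plus a JSON margin sidecar", {
  net <- interactionMatrix(matrix(c(3, 1, 1, 3), 2,
                                  dimnames = list(c("a", "b"), c("x", "y"))))
  path <- withr::local_tempfile(fileext = ".csv")
  exportInteractionMatrix(net, path)
  back <- read.csv(path)
  expect_equal(back$x, c(3, 1))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$grand_total, 8)
  expect_equal(side$col_totals$y, 4)
})
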