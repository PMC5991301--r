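monthly_temps <- function() oribatidMonthlyConditions()$temp_mean

test_that("monthly proportions normalize pooled abundances", {
  ds <- communityDataset(make_survey(
    list("a", "moss", 7, 1, 5, 0.01),
    list("b", "moss", 3, 1, 30, 1), list("b", "litter", 9, 1, 10, 1)))
  pA <- monthlyProportions(ds, "a")
  expect_equal(unname(pA[7]), 1)
  expect_equal(sum(pA), 1)
  pB <- monthlyProportions(ds, "b")
  expect_equal(unname(pB[c(3, 9)]), c(0.75, 0.25))
  expect_error(monthlyProportions(ds, "zz"), "not present")

  # equal abundance in all 12 months
  rows <- lapply(1:12, function(m) list("c", "moss", m, 1, 4, 0.1))
  dsu <- communityDataset(do.call(make_survey, rows))
  expect_equal(unname(monthlyProportions(dsu, "c")), rep(1 / 12, 12))
})

test_that("the weighted occurrence mean matches its defining sum product", {
  temps <- monthly_temps()
  pJuly <- replace(rep(0, 12), 7, 1)
  expect_equal(weightedNiche(pJuly, temps), 17.0)
  expect_equal(weightedNiche(rep(1 / 12, 12), temps), 10.225)
  expect_equal(weightedNiche(c(0.5, 0.5), c(0, 10)), 5)
  expect_error(weightedNiche(c(0.6, 0.5), c(0, 10)), "sum to 1")
  expect_error(weightedNiche(pJuly, replace(temps, 7, NA)), "missing")

  # mu is bounded by the environmental range over occupied months
  set.seed(14)
  for (i in 1:20) {
    p <- rgamma(12, 1); p <- p / sum(p)
    mu <- weightedNiche(p, temps)
    expect_gte(mu, min(temps[p > 0]))
    expect_lte(mu, max(temps[p > 0]))
  }
})

test_that("niche breadth is the weighted SD of the occupied months", {
  temps <- monthly_temps()
  pJuly <- replace(rep(0, 12), 7, 1)
  expect_equal(nicheBreadth(pJuly, temps), 0)
  expect_equal(nicheBreadth(c(0.5, 0.5), c(0, 10)), 5)
  expect_equal(nicheBreadth(c(0.75, 0.25), c(0, 10)),
               sqrt(0.75 * 6.25 + 0.25 * 56.25))
  expect_equal(nicheBreadth(c(0.75, 0.25), c(0, 10)), 4.330, tolerance = 1e-3)
})

test_that("permutation nulls behave at the enumerated extremes", {
  temps <- monthly_temps()
  # permutation-invariant profile: p exactly 1
  uniform <- nicheNullTest(rep(1 / 12, 12), temps, nIter = 299, seed = 1)
  expect_equal(pValue(uniform), 1)

  # strictly monotone alignment attains the two-sided floor 2/(n+1)
  ord <- rank(temps)
  p <- ord / sum(ord)
  floorTest <- nicheNullTest(p, temps, nIter = 999, seed = 2)
  expect_lte(pValue(floorTest), 4 / 1000)

  # a point mass ties with the 1/12 of permutations that reproduce it,
  # so its two-sided p concentrates near 2/12 (not the absolute floor)
  pm <- replace(rep(0, 12), which.max(temps), 1)
  pmTest <- nicheNullTest(pm, temps, nIter = 4999, seed = 3)
  expect_gt(pValue(pmTest), 0.10)
  expect_lt(pValue(pmTest), 0.25)

  expect_error(nicheNullTest(pm, rep(5, 12)), "constant")

  # multinomial null is exposed as an alternative
  alt <- nicheNullTest(p, temps, nIter = 299, seed = 4,
                       nullModel = "multinomial")
  expect_s4_class(alt, "NullEnsemble")
  expect_lte(pValue(alt), 1)
})

test_that("niche classification applies the significance and delta rules", {
  expect_equal(classifyNiche(17.0, 0.001, 10.2), "warmer")
  expect_equal(classifyNiche(3.0, 0.001, 10.2), "colder")
  expect_equal(classifyNiche(10.3, 0.001, 10.2), "neutral")
  expect_equal(classifyNiche(17.0, 0.4, 10.2), "none")
  expect_equal(classifyNiche(95, 0.01, 88, delta = 1, variable = "humidity"),
               "wetter")
  expect_equal(classifyNiche(60, 0.01, 88, delta = 1, variable = "humidity"),
               "drier")
})

test_that("dataset-level niche estimation is deterministic and complete", {
  sim <- generateCommunity(syntheticConfig(nTaxa = 12, nReplicates = 3),
                           seed = 8)
  temps <- sim$weather$summary$theta_m
  tab <- estimateNiches(sim$dataset, temps, "temperature",
                        nIter = 199, seed = 42)
  expect_equal(nrow(tab), length(taxa(sim$dataset)))
  expect_true(all(tab$mu >= min(temps) - 1e-9 & tab$mu <= max(temps) + 1e-9))
  expect_true(all(tab$category %in% c("warmer", "colder", "neutral", "none")))
  expect_true(all(tab$reliable == (tab$months_present >= 2)))
  tab2 <- estimateNiches(sim$dataset, temps, "temperature",
                         nIter = 199, seed = 42)
  expect_identical(tab, tab2)
})
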