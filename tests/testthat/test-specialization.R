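test_that("two-dimensional entropy matches hand-computed values", {
  expect_equal(twoDimEntropy(matrix(c(4, 0, 0, 4), 2)), log(2))
  expect_equal(twoDimEntropy(matrix(1, 2, 2)), log(4))
  h <- -2 * (3 / 8 * log(3 / 8)) - 2 * (1 / 8 * log(1 / 8))
  expect_equal(twoDimEntropy(matrix(c(3, 1, 1, 3), 2)), h)
  expect_equal(h, 1.2555, tolerance = 1e-4)
  expect_error(twoDimEntropy(matrix(0, 2, 2)), "all-zero")
})

test_that("entropy extrema bracket all feasible tables for small margins", {
  ex <- h2Extrema(c(4, 4), c(4, 4))
  expect_equal(unname(ex["h2Max"]), log(4))
  expect_equal(unname(ex["h2Min"]), log(2))
  # brute force over the 1-parameter family of 2x2 tables with margins 4/4
  ents <- sapply(0:4, function(x) oracle_entropy(c(x, 4 - x, 4 - x, x)))
  expect_equal(unname(ex["h2Min"]), min(ents))
  expect_equal(unname(ex["h2Max"]), max(ents))

  # one-row margins leave no freedom
  ex1 <- h2Extrema(8, c(4, 4))
  expect_equal(unname(ex1["h2Min"]), unname(ex1["h2Max"]))
  expect_equal(unname(ex1["h2Min"]), log(2))

  # greedy trace for margins (6,2)/(6,2): concentrated table [[6,0],[0,2]]
  ex2 <- h2Extrema(c(6, 2), c(6, 2))
  expect_equal(unname(ex2["h2Min"]), oracle_entropy(c(6, 0, 0, 2)))
  ents2 <- sapply(0:2, function(x)
    oracle_entropy(c(6 - x, x, x, 2 - x)))  # a11 = 6-x parametrization
  expect_equal(unname(ex2["h2Min"]), min(ents2))

  expect_error(h2Extrema(c(4, 4), c(4, 3)), "equal sums")
  expect_error(h2Extrema(c(-1, 4), c(2, 1)), "nonnegative")
})

test_that("greedy minimum never undercuts the exhaustive minimum", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    rt <- as.vector(oracle_compositions(n, sample(2:3, 1))[1, ])
    rt <- sample(seq_len(n - 1), sample(2:3, 1)) # random-ish margins
    rt <- rt[rt > 0]
    ct <- as.vector(tabulate(sample(seq_along(rt), sum(rt), replace = TRUE),
                             nbins = length(rt)))
    if (any(ct == 0) || sum(ct) != sum(rt)) next
    g <- unname(h2Extrema(rt, ct)["h2Min"])
    expect_gte(g + 1e-9, oracle_min_entropy(rt, ct))
  }
})

test_that("H2' is 0 at independence, 1 at perfect specialization", {
  expect_equal(specializationIndex(h2Prime(matrix(1, 2, 2))), 0)
  expect_equal(specializationIndex(h2Prime(matrix(c(4, 0, 0, 4), 2))), 1)
  res <- h2Prime(matrix(c(3, 1, 1, 3), 2))
  expect_s4_class(res, "SpecializationResult")
  expect_gt(res@h2Prime, 0)
  expect_lt(res@h2Prime, 1)
  # degenerate margins: single row
  m <- matrix(c(4, 4), 1, dimnames = list("a", c("x", "y")))
  expect_warning(r1 <- h2Prime(m), "degenerate")
  expect_equal(specializationIndex(r1), 0)
  expect_true(r1@degenerate)
})

test_that("H2' stays in [0,1] and is invariant to global rescaling", {
  set.seed(11)
  for (i in 1:15) {
    v <- matrix(rgamma(12, 0.6), 4, 3)
    v[sample(12, 3)] <- 0
    if (any(rowSums(v) == 0)) v[rowSums(v) == 0, 1] <- 0.5
    hp <- specializationIndex(h2Prime(v))
    expect_gte(hp, 0)
    expect_lte(hp, 1)
    expect_equal(specializationIndex(h2Prime(v * 7.3)), hp, tolerance = 1e-9)
  }
})

test_that("node KL divergence follows its closed forms", {
  m <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  d <- nodeKLDivergence(m, "x")
  expect_equal(d, 0.75 * log(1.5) + 0.25 * log(0.5))
  expect_equal(d, 0.1308, tolerance = 1e-4)

  # proportional column: divergence 0
  prop <- outer(c(5, 2, 3), c(2, 1))
  dimnames(prop) <- list(letters[1:3], c("x", "y"))
  expect_equal(nodeKLDivergence(prop, "x"), 0)
  expect_equal(nodeKLDivergence(prop, "y"), 0)

  # single-taxon column: point-mass KL is log(m / A_taxon)
  v <- matrix(rpois(20, 5) + 1, 10, 2,
              dimnames = list(paste0("t", 1:10), c("x", "y")))
  v[, 2] <- 0
  v[4, 2] <- 9
  A4 <- sum(v[4, ])
  expect_equal(nodeKLDivergence(v, "y"), log(sum(v) / A4))
  expect_error(nodeKLDivergence(m, "nope"), "unknown habitat")
})

test_that("d' standardizes KL between proportional and exclusive limits", {
  m <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  dp <- dPrime(m, "x")
  expect_s4_class(dp, "NodeSpecialization")
  expect_equal(specializationIndex(dp), (0.75 * log(1.5) + 0.25 * log(0.5)) / log(2))
  expect_equal(specializationIndex(dp), 0.1887, tolerance = 1e-3)

  prop <- outer(c(5, 2, 3), c(2, 1))
  dimnames(prop) <- list(letters[1:3], c("x", "y"))
  for (h in c("x", "y"))
    expect_equal(specializationIndex(dPrime(prop, h)), 0)

  # outer-product property on random margins
  set.seed(21)
  for (i in 1:10) {
    v <- outer(rgamma(5, 2), rgamma(3, 2))
    dimnames(v) <- list(paste0("t", 1:5), paste0("h", 1:3))
    for (h in colnames(v))
      expect_equal(specializationIndex(dPrime(v, h)), 0, tolerance = 1e-9)
  }

  # a habitat holding all mass has no defined exclusiveness
  solo <- matrix(c(4, 3, 0, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(dPrime(solo, "y"), "column total")
  solo1 <- matrix(c(4, 3), 2, dimnames = list(c("a", "b"), "x"))
  expect_warning(dp1 <- dPrime(solo1, "x"), "all")
  expect_equal(specializationIndex(dp1), 0)
})

test_that("integer-mode d' bounds bracket the continuous divergence", {
  m <- matrix(c(30, 10, 10, 30), 2, dimnames = list(c("a", "b"), c("x", "y")))
  dpI <- dPrime(m, "x", mode = "integer")
  dpC <- dPrime(m, "x", mode = "continuous")
  expect_gte(specializationIndex(dpI), 0)
  expect_lte(specializationIndex(dpI), 1)
  expect_lte(dpI@dMax, dpC@dMax + 1e-9)  # row caps tighten the upper bound
  expect_gte(dpI@dMin, 0)
})

test_that("pairwise H2' distance separates identical from disjoint columns", {
  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  rownames(same) <- letters[1:3]
  expect_equal(pairwiseH2Distance(same, c("x", "y")), 0)

  disjoint <- cbind(x = c(3, 1, 0, 0), y = c(0, 0, 2, 5))
  rownames(disjoint) <- letters[1:4]
  expect_equal(pairwiseH2Distance(disjoint, c("x", "y")), 1)

  m <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(pairwiseH2Distance(m, c("x", "y")),
               specializationIndex(h2Prime(m)))

  tri <- cbind(x = c(3, 1), y = c(1, 3), z = c(1, 1))
  rownames(tri) <- c("a", "b")
  expect_equal(pairwiseH2Distance(tri, c("x", "y")), 0.1887, tolerance = 1e-3)
  expect_error(pairwiseH2Distance(tri, c("x", "x", "y")), "exactly two")
})

test_that("Patefield sampling conserves margins and is uniform on 2x2", {
  expect_equal(patefieldSample(1, 1), matrix(1, 1, 1))

  set.seed(5)
  draws <- patefieldSample(c(1, 1), c(1, 1), n = 10000, seed = 17)
  a11 <- vapply(draws, function(d) d[1, 1], numeric(1))
  expect_true(all(a11 %in% c(0, 1)))
  # two feasible tables, each with frequency 1/2 (3 SE band at n = 10000)
  expect_equal(mean(a11), 0.5, tolerance = 3 * 0.5 / sqrt(10000))

  r <- c(7, 3, 9); cc <- c(6, 8, 5)
  for (d in patefieldSample(r, cc, n = 50, seed = 2)) {
    expect_equal(rowSums(d), r)
    expect_equal(colSums(d), cc)
  }
  expect_error(patefieldSample(c(2, 1), c(1, 1)), "equal sums")
  expect_error(patefieldSample(c(1.5, 0.5), c(1, 1)), "integer")
})

test_that("H2' null test flags specialization against fixed-margin draws", {
  diagm <- diag(c(30, 30, 30))
  dimnames(diagm) <- list(paste0("t", 1:3), paste0("h", 1:3))
  nt <- nullTestH2(interactionMatrix(diagm, "count"), nIter = 499, seed = 3)
  expect_s4_class(nt, "NullEnsemble")
  expect_equal(pValue(nt), 1 / 500)  # smallest attainable with add-one
  expect_equal(nt@observed, 1)

  # an independence-like table sits inside its null distribution
  outerTab <- round(outer(c(40, 25, 35), c(30, 45, 25)) / 100)
  dimnames(outerTab) <- list(paste0("t", 1:3), paste0("h", 1:3))
  nt2 <- nullTestH2(interactionMatrix(outerTab, "count"), nIter = 499, seed = 3)
  expect_gt(pValue(nt2), 0.1)
  expect_lt(abs(nt2@observed - mean(nullDraws(nt2))),
            3 * sd(nullDraws(nt2)))

  expect_warning(nullTestH2(interactionMatrix(diagm, "count"), nIter = 50,
                            seed = 1), "small")
})

test_that("specialization-generated communities reject the neutral null", {
  sim <- generateCommunity(syntheticConfig(nTaxa = 20, nReplicates = 3,
                                           preferenceMode = "onehot"),
                           seed = 9)
  cnt <- buildInteractionMatrix(sim$dataset, valueMode = "count")
  nt <- nullTestH2(cnt, nIter = 1999, seed = 23)
  expect_lt(pValue(nt), 0.001)
  expect_gt(nt@observed, max(nullDraws(nt)))
})

test_that("pairwise H2' tests separate shared from disjoint communities", {
  same <- cbind(x = c(30, 10, 20), y = c(30, 10, 20))
  rownames(same) <- letters[1:3]
  tSame <- pairwiseH2Test(interactionMatrix(same, "count"), c("x", "y"),
                          nIter = 499, seed = 4)
  expect_gt(pValue(tSame), 0.5)

  disjoint <- cbind(x = c(30, 10, 0, 0), y = c(0, 0, 20, 50))
  rownames(disjoint) <- letters[1:4]
  tDis <- pairwiseH2Test(interactionMatrix(disjoint, "count"), c("x", "y"),
                         nIter = 499, seed = 4)
  expect_equal(pValue(tDis), 1 / 500)
})

test_that("pairwise H2' p-values are well calibrated under the margins null", {
  set.seed(77)
  r <- c(12, 18, 25, 9, 16); cc <- c(40, 40)
  pvals <- vapply(1:120, function(i) {
    tab <- stats::r2dtable(1, r, cc)[[1]]
    dimnames(tab) <- list(paste0("t", 1:5), c("x", "y"))
    pValue(suppressWarnings(
      pairwiseH2Test(interactionMatrix(tab, "count"), c("x", "y"),
                     nIter = 99)))
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lte(mean(pvals < 0.05), 0.12)
})
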