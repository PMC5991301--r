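#' @include community-data.R
NULL

#' Two-dimensional Shannon entropy of an interaction matrix
#'
#' `H2 = -sum_{a_ij > 0} (a_ij / m) log(a_ij / m)` over the cells of the
#' weighted bipartite matrix, in nats.
#'
#' @param matrix an [InteractionMatrix-class] or a plain nonnegative matrix.
#' @return entropy in nats.
#' @export
twoDimEntropy <- function(matrix) {
  v <- if (methods::is(matrix, "InteractionMatrix")) matrix@values else as.matrix(matrix)
  .entropy(v)
}

# Greedy concentration heuristic: repeatedly allocate
# min(remaining row, remaining col) to the currently largest-remaining
# row/column pair (ties broken at the lowest index) until the margins are
# exhausted. Yields a maximally concentrated table; its entropy is the
# h2Min heuristic. Known not to attain the true minimum on every margin
# configuration (the published index uses the same kind of heuristic).
.greedyConcentrate <- function(rowTotals, colTotals) {
  M <- matrix(0, length(rowTotals), length(colTotals))
  r <- as.numeric(rowTotals)
  cc <- as.numeric(colTotals)
  total <- sum(r)
  eps <- 1e-12 * max(1, total)
  while (sum(r) > eps) {
    i <- which.max(r)
    j <- which.max(cc)
    a <- min(r[i], cc[j])
    M[i, j] <- M[i, j] + a
    r[i] <- r[i] - a
    cc[j] <- cc[j] - a
  }
  M
}

# Most-even integer table honoring the margins: start from the rounded-down
# independence expectation and hand the remaining individuals, one at a
# time, to the cell with the largest residual expectation that still has
# row and column capacity.
.evenIntegerTable <- function(rowTotals, colTotals) {
  r <- as.numeric(rowTotals)
  cc <- as.numeric(colTotals)
  m <- sum(r)
  E <- outer(r, cc) / m
  M <- floor(E)
  # trim any row/col overshoot from flooring (cannot overshoot), then fill
  rFree <- r - rowSums(M)
  cFree <- cc - colSums(M)
  resid <- E - M
  while (sum(rFree) > 0) {
    ok <- outer(rFree > 0, cFree > 0, "&")
    if (!any(ok)) break
    cand <- resid
    cand[!ok] <- -Inf
    idx <- which(cand == max(cand), arr.ind = TRUE)[1, , drop = TRUE]
    M[idx[1], idx[2]] <- M[idx[1], idx[2]] + 1
    resid[idx[1], idx[2]] <- resid[idx[1], idx[2]] - 1
    rFree[idx[1]] <- rFree[idx[1]] - 1
    cFree[idx[2]] <- cFree[idx[2]] - 1
  }
  M
}

#' Entropy extrema of tables with fixed margins
#'
#' Bounds of the two-dimensional Shannon entropy over tables with the given
#' row and column totals, used to standardize H2 into H2'.
#'
#' In `"continuous"` mode `h2Max` is the entropy of the outer product of
#' the marginal shares (the independence table; equal to row entropy plus
#' column entropy, and an exact maximum), and `h2Min` is the entropy of the
#' greedy concentration heuristic: repeatedly allocate
#' `min(remaining row, remaining col)` to the currently largest-remaining
#' row/column pair. In `"integer"` mode the same heuristics run on integer
#' tables: the margins are rounded, the maximum table distributes
#' individuals as evenly as the integer margins allow, and the greedy
#' minimum operates on the integer margins.
#'
#' @param rowTotals,colTotals positive margins with equal sums (relative
#'   mismatch beyond 1e-9 is an error).
#' @param mode `"continuous"` (default) or `"integer"`.
#' @return named numeric `c(h2Min, h2Max)`.
#' @export
h2Extrema <- function(rowTotals, colTotals, mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (any(rowTotals < 0) || any(colTotals < 0))
    stop("margins must be nonnegative")
  sr <- sum(rowTotals)
  sc <- sum(colTotals)
  if (sr <= 0 || sc <= 0) stop("margins must have positive sums")
  if (abs(sr - sc) > 1e-9 * max(sr, sc))
    stop(sprintf("row and column margins must have equal sums (%g vs %g)", sr, sc))
  if (mode == "integer") {
    rowTotals <- round(rowTotals)
    colTotals <- round(colTotals)
    # rounding can desynchronize the sums; reconcile on the larger side
    dr <- sum(rowTotals) - sum(colTotals)
    if (dr > 0) colTotals[which.max(colTotals)] <- colTotals[which.max(colTotals)] + dr
    if (dr < 0) rowTotals[which.max(rowTotals)] <- rowTotals[which.max(rowTotals)] - dr
    h2Max <- .entropy(.evenIntegerTable(rowTotals, colTotals))
  } else {
    h2Max <- .entropy(rowTotals) + .entropy(colTotals)
  }
  h2Min <- .entropy(.greedyConcentrate(rowTotals, colTotals))
  c(h2Min = h2Min, h2Max = min(h2Max, .entropy(rowTotals) + .entropy(colTotals)))
}

#' Complementary specialization H2' of a bipartite network
#'
#' Standardizes the two-dimensional Shannon entropy of the matrix between
#' its margin-constrained extrema:
#' `H2' = (h2Max - H2) / (h2Max - h2Min)`, clipped into `[0, 1]`.
#' 0 means the taxa use the habitats in proportion to overall availability
#' (maximal generalization); 1 means perfectly complementary use.
#' When the margins leave no freedom (`h2Max == h2Min`) the index is
#' defined as 0 and flagged degenerate.
#'
#' @param matrix an [InteractionMatrix-class] or plain nonnegative matrix.
#' @param mode extremum heuristics, `"continuous"` (default) or `"integer"`.
#' @return a [SpecializationResult-class].
#' @examples
#' h2Prime(matrix(c(4, 0, 0, 4), 2))  # perfect specialization: 1
#' h2Prime(matrix(1, 2, 2))           # independence: 0
#' @export
h2Prime <- function(matrix, mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  h2 <- twoDimEntropy(matrix)
  ex <- h2Extrema(matrix@rowTotals, matrix@colTotals, mode = mode)
  # the extrema come from heuristics: the observed table can (rarely) fall
  # outside them, in which case the observed value is the better bound
  h2Min <- min(unname(ex["h2Min"]), h2)
  h2Max <- max(unname(ex["h2Max"]), h2)
  degenerate <- (h2Max - h2Min) <= 1e-9
  if (degenerate) {
    warning("degenerate margins: h2Max == h2Min; H2' defined as 0")
    hp <- 0
  } else {
    hp <- (h2Max - h2) / (h2Max - h2Min)
    hp <- min(1, max(0, hp))
  }
  methods::new("SpecializationResult",
    h2 = h2, h2Min = h2Min, h2Max = h2Max,
    h2Prime = unname(hp), mode = mode, degenerate = unname(degenerate))
}

#' Kullback-Leibler divergence of one habitat's taxon use
#'
#' For habitat column h: `d = sum_{p'_j > 0} p'_j log(p'_j / q_j)` where
#' `p'_j = a[j, h] / B_h` is the share of the habitat's individuals found in
#' taxon j and `q_j = A_j / m` is taxon j's overall availability. Zero when
#' the habitat samples taxa proportionally to availability.
#'
#' @param matrix an [InteractionMatrix-class] or plain matrix.
#' @param node habitat column name or index.
#' @return divergence in nats, `>= 0`.
#' @export
nodeKLDivergence <- function(matrix, node) {
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  v <- matrix@values
  if (is.character(node) && !node %in% colnames(v))
    stop(sprintf("unknown habitat '%s'", node))
  col <- v[, node]
  Bh <- sum(col)
  if (Bh <= 0) stop("node column total must be > 0")
  p <- col / Bh
  q <- matrix@rowTotals / matrix@grandTotal
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# Integer-mode d bounds per the allocation heuristics used for the
# published index: dMin from the integer table closest to proportional
# allocation, dMax from concentrating the column on the taxa with the
# smallest overall availability (capped by their row totals).
.dBoundsInteger <- function(rowTotals, m, Bh) {
  q <- rowTotals / m
  # dMin: largest-remainder rounding of proportional allocation q * Bh
  exact <- q * Bh
  alloc <- floor(pmin(exact, rowTotals))
  left <- Bh - sum(alloc)
  if (left > 0) {
    room <- rowTotals - alloc
    resid <- exact - alloc
    ord <- order(resid, decreasing = TRUE)
    for (i in ord) {
      if (left == 0) break
      take <- min(left, room[i], 1)
      alloc[i] <- alloc[i] + take
      left <- left - take
    }
    # if single-unit passes left something, loop again greedily
    while (left > 0) {
      room <- rowTotals - alloc
      i <- which.max(room)
      take <- min(left, room[i])
      alloc[i] <- alloc[i] + take
      left <- left - take
    }
  }
  kl <- function(a) {
    p <- a[a > 0] / sum(a)
    sum(p * log(p / q[a > 0]))
  }
  dMin <- kl(alloc)
  # dMax: fill from the rarest taxa upward
  allocMax <- numeric(length(rowTotals))
  left <- Bh
  for (i in order(rowTotals)) {
    if (left == 0) break
    take <- min(left, rowTotals[i])
    allocMax[i] <- take
    left <- left - take
  }
  dMax <- kl(allocMax)
  c(dMin = dMin, dMax = dMax)
}

#' Standardized Kullback-Leibler specialization d' of a habitat
#'
#' Standardizes [nodeKLDivergence()] between its feasibility bounds:
#' in `"continuous"` mode `dMin = 0` (proportional allocation is feasible)
#' and `dMax = log(m / B_h)` (a point mass on the rarest achievable
#' configuration); `d' = (d - dMin) / (dMax - dMin)`, clipped into
#' `[0, 1]`. In `"integer"` mode both bounds come from integer allocation
#' heuristics honoring the row totals. A habitat holding all the mass has
#' `dMax = 0`; its d' is defined as 0 with a warning.
#'
#' @inheritParams nodeKLDivergence
#' @param mode `"continuous"` (default) or `"integer"`.
#' @return a [NodeSpecialization-class].
#' @export
dPrime <- function(matrix, node, mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  d <- nodeKLDivergence(matrix, node)
  Bh <- sum(matrix@values[, node])
  m <- matrix@grandTotal
  if (mode == "continuous") {
    dMin <- 0
    dMax <- log(m / Bh)
  } else {
    b <- .dBoundsInteger(round(matrix@rowTotals), round(m), round(Bh))
    dMin <- unname(b["dMin"])
    dMax <- unname(b["dMax"])
  }
  degenerate <- (dMax - dMin) <= 1e-9
  if (degenerate) {
    warning("node holds (nearly) all interaction mass; d' defined as 0")
    dp <- 0
  } else {
    dp <- min(1, max(0, (d - dMin) / (dMax - dMin)))
  }
  nodeName <- if (is.character(node)) node else colnames(matrix@values)[node]
  methods::new("NodeSpecialization",
    node = nodeName, d = d, dMin = dMin, dMax = max(dMax, d),
    dPrime = dp, mode = mode, degenerate = degenerate)
}

#' Pairwise H2' distance between two habitats
#'
#' The complementary specialization of the two-column submatrix restricted
#' to the chosen habitat pair (taxa absent from both columns are dropped).
#' 0 when the two habitats host identical taxon distributions, 1 when
#' their taxon sets are disjoint.
#'
#' @param matrix an [InteractionMatrix-class] or plain matrix.
#' @param pair length-2 vector of habitat names or indices.
#' @param mode extremum heuristics for the standardization.
#' @return numeric in `[0, 1]`.
#' @export
pairwiseH2Distance <- function(matrix, pair, mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  v <- matrix@values[, pair, drop = FALSE]
  if (ncol(v) != 2) stop("'pair' must select exactly two habitats")
  if (any(colSums(v) <= 0)) stop("both habitat columns must be nonzero")
  sub <- interactionMatrix(v, valueMode = matrix@valueMode)
  res <- h2Prime(sub, mode = mode)
  res@h2Prime
}

#' Draw random tables with fixed margins (Patefield RxC randomization)
#'
#' Uniform sampling of nonnegative integer tables with exactly the given
#' row and column sums, via Patefield's sequential conditional algorithm
#' (delegated to [stats::r2dtable()]). This is the fixed-margin null model
#' behind all network randomization tests in the package.
#'
#' @param rowTotals,colTotals nonnegative integer margins with equal sums.
#' @param n number of tables to draw, default 1.
#' @param seed optional integer seed.
#' @return a single matrix when `n == 1`, else a list of matrices.
#' @export
patefieldSample <- function(rowTotals, colTotals, n = 1, seed = NULL) {
  r <- as.numeric(rowTotals)
  cc <- as.numeric(colTotals)
  if (any(r < 0) || any(cc < 0)) stop("margins must be nonnegative")
  if (any(abs(r - round(r)) > 1e-9) || any(abs(cc - round(cc)) > 1e-9))
    stop("Patefield sampling requires integer margins")
  if (abs(sum(r) - sum(cc)) > 1e-9)
    stop(sprintf("row and column margins must have equal sums (%g vs %g)",
                 sum(r), sum(cc)))
  if (length(r) == 1 || length(cc) == 1) {
    # a single row or column leaves no freedom: the table is forced
    forced <- matrix(if (length(r) == 1) round(cc) else round(r),
                     nrow = length(r), ncol = length(cc))
    draws <- rep(list(forced), n)
  } else {
    draws <- .withSeed(seed, stats::r2dtable(n, round(r), round(cc)))
  }
  if (n == 1) draws[[1]] else draws
}

# Shared engine for the H2' null tests: integer counts are required, so
# density matrices are rounded to the nearest individual before
# randomization (the index itself is computed on the rounded table for
# observed and null alike, keeping the comparison apples-to-apples).
.nullTestEngine <- function(matrix, nIter, seed, mode, statistic) {
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "count")
  if (nIter < 100)
    warning(sprintf("nIter = %d is very small for a permutation test", nIter))
  v <- matrix@values
  if (matrix@valueMode == "density") v <- round(v)
  keep <- rowSums(v) > 0
  v <- v[keep, , drop = FALSE]
  if (sum(v) <= 0) stop("rounded count matrix is empty")
  counts <- interactionMatrix(v, valueMode = "count")
  observed <- h2Prime(counts, mode = mode)@h2Prime
  r <- round(counts@rowTotals)
  cc <- round(counts@colTotals)
  draws <- .withSeed(seed, stats::r2dtable(nIter, r, cc))
  nullVals <- vapply(draws, function(d) {
    dimnames(d) <- dimnames(v)
    suppressWarnings(h2Prime(interactionMatrix(d, valueMode = "count"),
                             mode = mode)@h2Prime)
  }, numeric(1))
  methods::new("NullEnsemble",
    statistic = statistic, observed = observed, nullDraws = nullVals,
    pValue = .permPValue(observed, nullVals, "greater"),
    nIter = nIter, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    alternative = "greater")
}

#' Fixed-margin null-model test of network specialization
#'
#' Compares the observed H2' against the H2' of `nIter` Patefield draws
#' with the observed margins (counts; densities are rounded to the nearest
#' individual first). The p-value is upper-tail with the add-one
#' correction: `p = (#{null >= observed} + 1) / (nIter + 1)`.
#'
#' @param matrix an [InteractionMatrix-class] (count mode, or densities to
#'   be rounded) or plain matrix.
#' @param nIter number of randomized networks, default 10000.
#' @param seed optional integer seed, recorded in the result.
#' @param mode extremum heuristics for H2'.
#' @return a [NullEnsemble-class] with statistic `"h2prime"`.
#' @export
nullTestH2 <- function(matrix, nIter = 10000, seed = NULL,
                       mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  .nullTestEngine(matrix, nIter, seed, mode, "h2prime")
}

#' Fixed-margin null test of a pairwise H2' distance
#'
#' [nullTestH2()] applied to the two-column submatrix of a habitat pair
#' (zero taxon rows dropped), testing whether the two habitats host more
#' complementary taxon distributions than their margins alone explain.
#'
#' @inheritParams pairwiseH2Distance
#' @param nIter number of randomized networks, default 1000.
#' @param seed optional integer seed.
#' @return a [NullEnsemble-class] with statistic `"pairwise_h2"`.
#' @export
pairwiseH2Test <- function(matrix, pair, nIter = 1000, seed = NULL,
                           mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "count")
  v <- matrix@values[, pair, drop = FALSE]
  if (ncol(v) != 2) stop("'pair' must select exactly two habitats")
  if (any(colSums(v) <= 0)) stop("both habitat columns must be nonzero")
  sub <- interactionMatrix(v, valueMode = matrix@valueMode)
  .nullTestEngine(sub, nIter, seed, mode, "pairwise_h2")
}
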