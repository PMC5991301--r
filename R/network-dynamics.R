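#' @include specialization.R
NULL

#' Neutral margin-product expectation of an interaction matrix
#'
#' `E[i, j] = A_i * B_j / m`: the interaction strengths expected if taxa
#' used habitats in proportion to overall availability. Sums to the grand
#' total.
#'
#' @param matrix an [InteractionMatrix-class] or plain matrix.
#' @return numeric matrix of expectations with the input's dimnames.
#' @export
neutralExpectation <- function(matrix) {
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  outer(matrix@rowTotals, matrix@colTotals) / matrix@grandTotal
}

#' Link temperature: standardized deviation from neutrality
#'
#' Standardizes each cell of the network by its deviation from the neutral
#' expectation `E = A_i B_j / m`:
#' `"relative"` (default) `t = (a - E) / E` — invariant to global
#' rescaling of the matrix; `"raw"` `t = a - E` — sums to zero over the
#' matrix; `"z_null"` `t = (a - mean_null) / sd_null` over fixed-margin
#' Patefield randomizations of the (rounded) count table, with cells of
#' zero null variance set to 0.
#'
#' @param matrix an [InteractionMatrix-class] or plain matrix.
#' @param method one of `"relative"`, `"raw"`, `"z_null"`.
#' @param nNull randomizations for `"z_null"`, default 200.
#' @param seed optional seed for `"z_null"`.
#' @return a [LinkTemperatureMatrix-class].
#' @export
linkTemperature <- function(matrix, method = c("relative", "raw", "z_null"),
                            nNull = 200, seed = NULL) {
  method <- match.arg(method)
  if (!methods::is(matrix, "InteractionMatrix"))
    matrix <- interactionMatrix(matrix, valueMode = "density")
  a <- matrix@values
  E <- neutralExpectation(matrix)
  if (any(E <= 0)) stop("neutral expectation has zero cells (empty margin?)")
  t <- switch(method,
    relative = (a - E) / E,
    raw = a - E,
    z_null = {
      counts <- round(a)
      draws <- .withSeed(seed,
        stats::r2dtable(nNull, round(rowSums(counts)), round(colSums(counts))))
      arr <- simplify2array(draws)
      mu <- apply(arr, c(1, 2), mean)
      sdv <- apply(arr, c(1, 2), stats::sd)
      z <- (counts - mu) / sdv
      z[!is.finite(z)] <- 0
      z
    })
  dimnames(t) <- dimnames(a)
  methods::new("LinkTemperatureMatrix", expected = E, t = t, method = method)
}

#' Permutation-tested correlation of two monthly networks
#'
#' Measures how similar the deviation structure of two consecutive monthly
#' networks is. Both matrices are restricted to their shared taxa, link
#' temperatures are computed per month from that month's own margins, and
#' the Pearson correlation over the aligned cells is the observed `r`.
#' The reported mean and SD of `r` come from bootstrap resamples of the
#' shared taxa (so two identical networks give r = 1 exactly); the
#' two-sided p-value comes from a fixed-margin (Patefield) null in which
#' the second network's cells are redrawn with its observed margins and
#' the link temperatures recomputed per draw.
#'
#' @param netA,netB [InteractionMatrix-class] objects sharing >= 3 taxa.
#' @param nPerm null permutations (and bootstrap replicates), default 1000.
#' @param seed optional integer seed.
#' @param method link-temperature method, default `"relative"`.
#' @param monthPair optional length-2 labels for reporting.
#' @return a [NetworkCorrelation-class].
#' @export
consecutiveCorrelation <- function(netA, netB, nPerm = 1000, seed = NULL,
                                   method = c("relative", "raw", "z_null"),
                                   monthPair = c("A", "B")) {
  method <- match.arg(method)
  if (!methods::is(netA, "InteractionMatrix"))
    netA <- interactionMatrix(netA, valueMode = "count")
  if (!methods::is(netB, "InteractionMatrix"))
    netB <- interactionMatrix(netB, valueMode = "count")
  shared <- intersect(rownames(netA@values), rownames(netB@values))
  if (length(shared) < 3)
    stop(sprintf("networks %s and %s share only %d taxa (>= 3 required)",
                 monthPair[1], monthPair[2], length(shared)))
  subA <- interactionMatrix(netA@values[shared, , drop = FALSE], netA@valueMode)
  subB <- interactionMatrix(netB@values[shared, , drop = FALSE], netB@valueMode)
  # taxa can drop out again if all their mass sat in unshared rows
  shared <- intersect(rownames(subA@values), rownames(subB@values))
  if (length(shared) < 3)
    stop(sprintf("networks %s and %s share only %d taxa with positive abundance",
                 monthPair[1], monthPair[2], length(shared)))
  tA <- linkTemperature(
    interactionMatrix(subA@values[shared, , drop = FALSE], subA@valueMode),
    method = method)@t
  tB <- linkTemperature(
    interactionMatrix(subB@values[shared, , drop = FALSE], subB@valueMode),
    method = method)@t
  rObs <- stats::cor(as.vector(tA), as.vector(tB))

  res <- .withSeed(seed, {
    # bootstrap over shared taxa for the dispersion of r
    nTaxa <- length(shared)
    boot <- vapply(seq_len(nPerm), function(k) {
      idx <- sample.int(nTaxa, nTaxa, replace = TRUE)
      suppressWarnings(stats::cor(as.vector(tA[idx, , drop = FALSE]),
                                  as.vector(tB[idx, , drop = FALSE])))
    }, numeric(1))
    # fixed-margin null on the second network
    vB <- round(subB@values[shared, , drop = FALSE])
    vB <- vB[rowSums(vB) > 0, , drop = FALSE]
    tASub <- tA[rownames(vB), , drop = FALSE]
    draws <- stats::r2dtable(nPerm, round(rowSums(vB)), round(colSums(vB)))
    nullR <- vapply(draws, function(d) {
      dimnames(d) <- dimnames(vB)
      keep <- rowSums(d) > 0
      tNull <- linkTemperature(interactionMatrix(d, "count"), method = method)@t
      suppressWarnings(stats::cor(as.vector(tASub[keep, , drop = FALSE]),
                                  as.vector(tNull)))
    }, numeric(1))
    list(boot = boot[is.finite(boot)], nullR = nullR[is.finite(nullR)])
  })
  methods::new("NetworkCorrelation",
    monthPair = as.character(monthPair),
    rObs = rObs,
    rMean = if (length(res$boot) > 0) mean(res$boot) else NA_real_,
    rSd = if (length(res$boot) > 1) stats::sd(res$boot) else NA_real_,
    pValue = .permPValue(rObs, res$nullR, "two.sided"),
    nPerm = nPerm,
    nShared = length(shared),
    method = method,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
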