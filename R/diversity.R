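#' @include community-data.R
NULL

#' Shannon entropy of an abundance vector
#'
#' `H = -sum p_s log(p_s)` in nats, with `p_s` the abundance shares; zero
#' entries contribute nothing. Delegates to [vegan::diversity()].
#'
#' @param abundances nonnegative numeric vector with at least one positive
#'   entry.
#' @return entropy in nats.
#' @export
shannonEntropy <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  if (sum(abundances) <= 0) stop("Shannon entropy undefined for an all-zero vector")
  as.numeric(vegan::diversity(abundances, index = "shannon"))
}

#' Effective Shannon diversity (effective number of species)
#'
#' `exp(H)`: the number of equally common taxa that would produce the
#' observed entropy. Equals richness for a perfectly even community and 1
#' for a monoculture.
#'
#' @inheritParams shannonEntropy
#' @return `exp(H)`, in `[1, richness]`.
#' @export
effectiveShannon <- function(abundances) {
  exp(shannonEntropy(abundances))
}

#' Species richness
#'
#' @inheritParams shannonEntropy
#' @return integer count of strictly positive entries.
#' @export
richness <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  sum(abundances > 0)
}

#' Per-group diversity summaries across replicates
#'
#' Computes, for every (microhabitat, month) group, the per-replicate
#' profile — total density (Ind/kg), richness and effective Shannon
#' diversity over taxa — and averages across replicates. The spread is the
#' standard error `SE = SD / sqrt(n)`, matching how per-sample community
#' parameters are usually displayed.
#'
#' @param dataset a [CommunityDataset-class].
#' @return tidy data.frame with columns `microhabitat`, `month`, `metric`
#'   (`abundance`, `richness`, `effective_shannon`), `mean`, `se`, `n`.
#' @export
summarizeByGroup <- function(dataset) {
  stopifnot(methods::is(dataset, "CommunityDataset"))
  rec <- dataset@records
  rec <- rec[rec$density > 0 | rec$raw_count == 0, , drop = FALSE]
  sampleKey <- interaction(rec$microhabitat, rec$month, rec$replicate, drop = TRUE)
  profiles <- do.call(rbind, lapply(split(rec, sampleKey), function(s) {
    data.frame(
      microhabitat = s$microhabitat[1],
      month = s$month[1],
      replicate = s$replicate[1],
      abundance = sum(s$density),
      richness = richness(s$density),
      effective_shannon = if (sum(s$density) > 0) effectiveShannon(s$density) else NA_real_
    )
  }))
  out <- do.call(rbind, lapply(
    split(profiles, interaction(profiles$microhabitat, profiles$month, drop = TRUE)),
    function(g) {
      do.call(rbind, lapply(c("abundance", "richness", "effective_shannon"),
        function(metric) {
          v <- g[[metric]]
          v <- v[!is.na(v)]
          data.frame(
            microhabitat = g$microhabitat[1],
            month = g$month[1],
            metric = metric,
            mean = mean(v),
            se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
            n = length(v)
          )
        }))
    }))
  rownames(out) <- NULL
  out[order(out$microhabitat, out$month, out$metric), ]
}
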