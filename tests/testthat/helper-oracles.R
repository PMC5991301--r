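# Independent oracles and tiny fixture builders used across the suite.

# Plain-R Shannon entropy of nonnegative weights (nats), 0 log 0 := 0.
oracle_entropy <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Exhaustive minimum entropy over all nonnegative integer tables with the
# given margins (recursion over rows; feasible only for tiny totals).
oracle_min_entropy <- function(rowTotals, colTotals) {
  best <- Inf
  nC <- length(colTotals)
  rec <- function(row, cfree, cells) {
    if (row > length(rowTotals)) {
      best <<- min(best, oracle_entropy(cells))
      return(invisible())
    }
    comp <- function(k, left, acc) {
      if (k == nC) {
        if (left <= cfree[k]) rec(row + 1, cfree - c(acc, left), c(cells, acc, left))
        return(invisible())
      }
      for (v in 0:min(left, cfree[k])) comp(k + 1, left - v, c(acc, v))
    }
    comp(1, rowTotals[row], integer(0))
  }
  rec(1, colTotals, numeric(0))
  best
}

# All compositions of n into k positive parts, one per row.
oracle_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (v in 1:(n - k + 1))
    out <- rbind(out, cbind(v, oracle_compositions(n - v, k - 1)))
  out
}

# Minimal long-format survey: each row list(taxon, habitat, month, rep,
# count, dw).
make_survey <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(taxon = r[[1]], microhabitat = r[[2]], month = r[[3]],
               replicate = r[[4]], raw_count = r[[5]], dry_weight_kg = r[[6]],
               stringsAsFactors = FALSE)))
}

# Deterministic multi-taxon dataset with exact densities: counts are
# density * dry weight with dry weight 0.01 kg, so densities are exact.
make_grid_dataset <- function(densities) {
  # densities: 3-d array [taxon, habitat, month]; one replicate
  dn <- dimnames(densities)
  rows <- expand.grid(taxon = dn[[1]], microhabitat = dn[[2]],
                      month = as.integer(dn[[3]]), stringsAsFactors = FALSE)
  rows$replicate <- 1L
  rows$dry_weight_kg <- 0.01
  rows$raw_count <- densities[cbind(rows$taxon, rows$microhabitat,
                                    as.character(rows$month))] * 0.01
  communityDataset(rows)
}

# Constant-weather series over `days` days before `date` for 4 loggers.
make_constant_weather <- function(date, days = 5, temp = 10, rh = 80) {
  t1 <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  times <- seq(t1 - days * 86400, t1 - 3600, by = 3600)
  do.call(rbind, lapply(1:4, function(l)
    data.frame(timestamp = times, logger_id = paste0("L", l),
               temp_c = temp, rh_pct = rh)))
}
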