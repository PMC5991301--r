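#' @include AllClasses.R
NULL

# Shannon entropy of a nonnegative weight vector/matrix (nats); 0*log 0 := 0.
.entropy <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("entropy requires nonnegative weights")
  s <- sum(x)
  if (s <= 0) stop("entropy undefined for an all-zero vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the global stream is consumed as-is.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Add-one permutation p-value. `alternative` integrates the documented tail.
.permPValue <- function(observed, draws, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(draws)
  pGreater <- (sum(draws >= observed) + 1) / (n + 1)
  pLess <- (sum(draws <= observed) + 1) / (n + 1)
  switch(alternative,
    greater = pGreater,
    less = pLess,
    two.sided = min(1, 2 * min(pGreater, pLess))
  )
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
  invisible(x)
}
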