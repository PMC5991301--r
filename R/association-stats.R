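#' @include utils.R
NULL

#' Simple linear regression with F-test
#'
#' Ordinary least squares of `y` on `x` with the overall F-statistic
#' (equivalently a Gaussian identity-link GLM). `F = (r2 / (1 - r2)) *
#' (n - 2)` with df `(1, n - 2)`; a perfect fit (zero residual variance)
#' reports `F = Inf` with `perfect_fit = TRUE`.
#'
#' @param x predictor vector (non-constant).
#' @param y response vector.
#' @return list with `slope`, `intercept`, `f_stat`, `df` (length 2),
#'   `p_value`, `r_squared`, `perfect_fit`.
#' @export
olsFTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  perfect <- tss > 0 && rss <= 1e-12 * tss
  fstat <- if (tss == 0) 0 else if (perfect) Inf else unname(sm$fstatistic["value"])
  pval <- if (tss == 0) 1 else if (perfect) 0 else
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    f_stat = fstat,
    df = c(1, n - 2),
    p_value = pval,
    r_squared = if (tss == 0) 0 else sm$r.squared,
    perfect_fit = perfect
  )
}

#' Wilks-lambda multivariate regression on one predictor
#'
#' One-way multivariate regression of an `n x k` response matrix on a
#' single continuous predictor, summarized by Wilks' lambda
#' `det(E) / det(E + H)` and Rao's exact F for one hypothesis df:
#' `F = ((1 - lambda) / lambda) * ((n - 1 - k) / k)` with df
#' `(k, n - 1 - k)`. Implemented via [stats::anova()] on a multivariate
#' linear model.
#'
#' @param Y numeric matrix of responses, one column per variable.
#' @param x predictor vector (non-constant), length `nrow(Y)`.
#' @return list with `wilks_lambda`, `f_approx`, `df` (length 2),
#'   `p_value`.
#' @export
wilksManova <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  if (length(x) != n) stop("x must match nrow(Y)")
  if (n <= k + 1) stop("need n > k + 1 observations")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(Y ~ x)
  tot <- crossprod(scale(Y, center = TRUE, scale = FALSE))
  if (abs(det(tot)) < 1e-300) stop("singular total SSCP matrix")
  if (k == 1) {
    # univariate case: lambda = RSS/TSS, Rao's F reduces to the OLS F
    lambda <- sum(stats::residuals(fit)^2) / as.numeric(tot)
    f <- (1 - lambda) / lambda * (n - 2)
    return(list(wilks_lambda = lambda, f_approx = f, df = c(1, n - 2),
                p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE)))
  }
  av <- stats::anova(fit, test = "Wilks")
  row <- which(rownames(av) == "x")
  lambda <- av[row, "Wilks"]
  list(
    wilks_lambda = lambda,
    f_approx = av[row, "approx F"],
    df = c(av[row, "num Df"], av[row, "den Df"]),
    p_value = av[row, "Pr(>F)"]
  )
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y numeric vectors, `n >= 4`, neither constant.
#' @return list with `rho`, `p_value` (t-approximation).
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("at least 4 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return list with `r`, `p_value` (t-test).
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
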