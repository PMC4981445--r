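## Statistical layer: Pearson correlations with Fisher-z confidence
## intervals, simple linear regression, SPSS-style stepwise multiple
## regression (probability-of-F entry/removal), Bland-Altman
## reproducibility and descriptive statistics.

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length >= 4 with finite values.
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return list with `r`, `ciLow`, `ciHigh`, `n`. For |r| = 1 the CI
#'   degenerates to the point r.
#' @export
pearsonCi <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance; correlation undefined")
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15)
    return(list(r = r, ciLow = r, ciHigh = r, n = n))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - alpha / 2)
  list(r = r, ciLow = tanh(z - q * se), ciHigh = tanh(z + q * se), n = n)
}

#' Simple linear regression
#'
#' Ordinary least squares of y on a single predictor, reporting R^2, the
#' adjusted R^2, the coefficients and the two-tailed p-value of the slope
#' (t distribution).
#'
#' @param x predictor; @param y response (equal length, n >= 3).
#' @return list with `r2`, `adjustedR2`, `coefficients` (intercept,
#'   slope), `p` (slope, two-tailed), `n`.
#' @export
simpleRegression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(r2 = sm$r.squared, adjustedR2 = sm$adj.r.squared,
       coefficients = coef(fit), p = sm$coefficients["x", "Pr(>|t|)"],
       n = n)
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) (n - 1) / (n - k - 1)`; may be negative.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations; @param k number of predictors.
#' @return scalar adjusted R^2.
#' @export
adjustedR2 <- function(r2, n, k) {
  if (n <= k + 1) stop("n must exceed k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Stepwise multiple linear regression (probability-of-F criteria)
#'
#' Forward entry of the candidate with the smallest entry p-value while
#' it is at most `pEnter`, followed after each entry by backward removal
#' of any included predictor whose partial p-value is at least `pRemove`
#' (the classic SPSS stepwise defaults: 0.05 in, 0.10 out). Entry and
#' removal p-values are the partial-F (equivalently t) tests of the
#' coefficient in the model containing the already-selected predictors.
#'
#' @param X data.frame or matrix of candidate predictors (>= 2 columns).
#' @param y response vector.
#' @param pEnter,pRemove entry/removal probability thresholds.
#' @return list with `selected` (ordered names), `steps` (log of
#'   entries/removals), `r2Single` (R^2 of the first selected predictor
#'   alone), `adjR2Two` (adjusted R^2 of the first two selected
#'   predictors; NA if fewer than two), `finalR2`, `finalAdjR2`, `n`, and
#'   `empty` (TRUE when no candidate passed entry).
#' @export
stepwiseRegression <- function(X, y, pEnter = 0.05, pRemove = 0.10) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 1)
  ok <- complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  candidates <- names(X)
  selected <- character(0)
  steps <- character(0)

  coefP <- function(vars) {
    df <- data.frame(y = y, X[, vars, drop = FALSE])
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    p <- sm[-1, "Pr(>|t|)"]
    names(p) <- vars
    p
  }

  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0 || length(selected) >= n - 2) break
    entryP <- vapply(pool, function(v) {
      p <- try(coefP(c(selected, v)), silent = TRUE)
      if (inherits(p, "try-error") || !is.finite(p[v])) 1 else p[[v]]
    }, numeric(1))
    best <- names(which.min(entryP))
    if (entryP[best] > pEnter) break
    selected <- c(selected, best)
    steps <- c(steps, paste0("+", best))
    # backward pass
    repeat {
      if (length(selected) == 0) break
      p <- coefP(selected)
      worst <- names(which.max(p))
      if (p[worst] >= pRemove) {
        selected <- setdiff(selected, worst)
        steps <- c(steps, paste0("-", worst))
      } else break
    }
  }

  if (length(selected) == 0)
    return(list(selected = character(0), steps = steps, r2Single = NA_real_,
                adjR2Two = NA_real_, finalR2 = NA_real_,
                finalAdjR2 = NA_real_, n = n, empty = TRUE))

  fitOf <- function(vars) {
    df <- data.frame(y = y, X[, vars, drop = FALSE])
    summary(lm(y ~ ., data = df))
  }
  r2Single <- fitOf(selected[1])$r.squared
  adjR2Two <- if (length(selected) >= 2)
    fitOf(selected[1:2])$adj.r.squared else NA_real_
  fin <- fitOf(selected)
  list(selected = selected, steps = steps, r2Single = r2Single,
       adjR2Two = adjR2Two, finalR2 = fin$r.squared,
       finalAdjR2 = fin$adj.r.squared, n = n, empty = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference), 1.96 SD limits of agreement and a
#' systematic-error flag (TRUE when 0 lies outside the t-based CI of the
#' bias).
#'
#' @param a,b paired measurement vectors (equal length >= 3).
#' @param alpha significance level for the bias CI.
#' @return list with `bias`, `loa` (lower, upper), `differences`,
#'   `systematic`, `n`.
#' @export
blandAltman <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  loa <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  se <- s / sqrt(n)
  ci <- bias + c(-1, 1) * qt(1 - alpha / 2, n - 1) * se
  systematic <- !(ci[1] <= 0 && 0 <= ci[2])
  if (s == 0) systematic <- bias != 0
  list(bias = bias, loa = loa, differences = d, systematic = systematic,
       n = n)
}

#' Column-wise descriptive statistics
#'
#' @param table data.frame; non-numeric columns are ignored.
#' @return data.frame with `column`, `mean`, `sd` (sample SD), `n`.
#' @export
descriptiveStats <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- names(table)[num]
  do.call(rbind, lapply(cols, function(cn) {
    v <- table[[cn]]
    v <- v[is.finite(v)]
    data.frame(column = cn, mean = mean(v), sd = sd(v), n = length(v))
  }))
}
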