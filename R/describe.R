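#' Descriptive statistics of a trait sample
#'
#' Mean, sample SD (n-1 denominator), coefficient of variation
#' `CV = 100 * sd / mean`, and bias-corrected (adjusted Fisher-Pearson, the
#' SPSS convention) sample skewness and excess kurtosis.
#'
#' @param values numeric vector, `n >= 2`.
#' @return a one-row data frame with `n`, `mean`, `sd`, `cv`, `skewness`,
#'   `kurtosis`. `cv` is `NA` for a zero mean; skewness/kurtosis are `NA`
#'   for constant samples or when `n` is too small for the bias correction
#'   (3 and 4 respectively).
#' @export
trait_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m == 0) NA_real_ else cv_percent(s, m)
  skew <- if (s == 0 || n < 3L) NA_real_ else e1071::skewness(values, type = 2)
  kurt <- if (s == 0 || n < 4L) NA_real_ else e1071::kurtosis(values, type = 2)
  data.frame(n = n, mean = m, sd = s, cv = cv, skewness = skew,
             kurtosis = kurt)
}

#' Coefficient of variation in percent
#'
#' @param sd sample standard deviation.
#' @param mean sample mean (non-zero).
#' @return `100 * sd / mean`.
#' @export
cv_percent <- function(sd, mean) {
  stopifnot(all(mean != 0))
  100 * sd / mean
}

#' Compare the two parent lines
#'
#' Welch's two-sample t-test with significance letters: the parents get
#' different letters (`"a"`/`"b"`, larger mean first) when `p < 0.05`, the
#' same letter otherwise. With only two groups the multiple-range letter
#' display reduces to this pairwise test.
#'
#' @param p1,p2 numeric vectors, each `n >= 2`.
#' @return list with `statistic`, `p_value`, `letters` (named for p1/p2).
#' @export
compare_parents <- function(p1, p2) {
  if (length(p1) < 2L || length(p2) < 2L) {
    stop("each parent group needs n >= 2", call. = FALSE)
  }
  if (stats::sd(p1) == 0 && stats::sd(p2) == 0) {
    p <- if (mean(p1) == mean(p2)) 1 else 0
    stat <- NA_real_
  } else {
    tt <- stats::t.test(p1, p2)
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  letters <- if (p < 0.05) {
    if (mean(p1) >= mean(p2)) c(p1 = "a", p2 = "b") else c(p1 = "b", p2 = "a")
  } else {
    c(p1 = "a", p2 = "a")
  }
  list(statistic = stat, p_value = p, letters = letters)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations with two-sided t-test p-values,
#' as used for the trait-by-trait correlation analysis of the stay-green
#' traits and grain yield.
#'
#' @param table numeric matrix or data frame, individuals in rows and traits
#'   in columns.
#' @return list with matrices `r`, `p` and `n` (complete pairs). Pairs
#'   involving a constant trait or fewer than 3 complete pairs are `NA`.
#' @export
correlation_matrix <- function(table) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("table must be numeric", call. = FALSE)
  p_traits <- ncol(X)
  r <- matrix(NA_real_, p_traits, p_traits,
              dimnames = list(colnames(X), colnames(X)))
  p <- r
  n <- matrix(NA_integer_, p_traits, p_traits,
              dimnames = dimnames(r))
  for (i in seq_len(p_traits)) {
    for (j in seq_len(i)) {
      ok <- stats::complete.cases(X[, i], X[, j])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < 3L) next
      xi <- X[ok, i]; xj <- X[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rij <- stats::cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      if (i == j) {
        p[i, j] <- 0
      } else {
        tstat <- rij * sqrt((nn - 2) / max(1 - rij^2, .Machine$double.eps))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), nn - 2)
      }
    }
  }
  list(r = r, p = p, n = n)
}
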