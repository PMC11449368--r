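# Goodness of fit of the fitted mixture, per generation, on the probability
# integral transform (PIT) scale: under a correct model the fitted-CDF values
# of the observations are U(0,1). The three uniformity statistics are Neyman
# smooth components on normalized shifted Legendre polynomials (departures in
# mean, spread and skewness of the PIT values), each asymptotically
# chi-square with 1 df; nW^2 is the Cramer-von Mises statistic and Dn the
# Kolmogorov sup-distance.

#' Probability integral transform under a fitted generation distribution
#'
#' @param values numeric observations for one generation.
#' @param spec either a full `"mixture_spec"` (then `generation` selects the
#'   component set) or a list with `means`, `weights`, `var`.
#' @param generation one of `"P1"`, `"P2"`, `"F1"`, `"F2"` when `spec` is a
#'   `"mixture_spec"`.
#' @return the fitted mixture CDF evaluated at each observation, in (0,1).
#' @export
pit <- function(values, spec, generation = NULL) {
  g <- if (inherits(spec, "mixture_spec")) {
    if (is.null(generation)) stop("generation must be given", call. = FALSE)
    spec[[match.arg(generation, GENERATIONS)]]
  } else {
    spec
  }
  mixture_cdf(values, g$means, g$weights, g$var)
}

# normalized shifted Legendre polynomials on (0,1), k = 1..3
neyman_poly <- function(e, k) {
  switch(k,
         sqrt(3) * (2 * e - 1),
         sqrt(5) * (6 * e^2 - 6 * e + 1),
         sqrt(7) * (20 * e^3 - 30 * e^2 + 12 * e - 1))
}

#' Uniformity, Cramer-von Mises and Kolmogorov statistics on PIT values
#'
#' `uniformity_stats()` returns the first three Neyman smooth components
#' `U1^2`, `U2^2`, `U3^2` (`n * mean(pi_k(e))^2`, each asymptotically
#' chi-square 1 under uniformity; 5% critical value 3.841). `cvm_stat()`
#' returns `nW^2 = 1/(12n) + sum(e_(i) - (2i-1)/(2n))^2` (5% point 0.461).
#' `ks_stat()` returns the sup-distance `Dn`.
#'
#' @param e PIT values in (0,1).
#' @return named numeric vector (`uniformity_stats`) or scalar.
#' @export
uniformity_stats <- function(e) {
  n <- length(e)
  stopifnot(n >= 1L)
  u <- vapply(1:3, function(k) n * mean(neyman_poly(e, k))^2, 0)
  names(u) <- c("U1sq", "U2sq", "U3sq")
  u
}

#' @rdname uniformity_stats
#' @export
cvm_stat <- function(e) {
  n <- length(e)
  stopifnot(n >= 1L)
  es <- sort(e)
  1 / (12 * n) + sum((es - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' @rdname uniformity_stats
#' @export
ks_stat <- function(e) {
  n <- length(e)
  stopifnot(n >= 1L)
  es <- sort(e)
  i <- seq_len(n)
  max(pmax(i / n - es, es - (i - 1) / n))
}

U_CRIT <- 3.841   # chi-square 1 df, 5%
CVM_CRIT <- 0.461 # asymptotic 5% point of the Cramer-von Mises statistic

ks_significant <- function(dn, n, e) {
  if (n < 35L) {
    # exact small-sample null distribution (one-sample Kolmogorov test)
    p <- suppressWarnings(stats::ks.test(e, "punif", exact = TRUE)$p.value)
    p < 0.05
  } else {
    dn > 1.358 / sqrt(n)
  }
}

#' Per-generation goodness-of-fit report for a fitted model
#'
#' Computes the five statistics for every generation present in the data,
#' with 5% significance flags (U-type against 3.841, nW^2 against 0.461, Dn
#' against its exact small-sample or asymptotic critical value).
#'
#' @param fit a `"seg_fit"`.
#' @param data the data the model was fitted to.
#' @return a data frame of class `"gof_report"` with one row per generation
#'   and columns `U1sq`, `U2sq`, `U3sq`, `nWsq`, `Dn` plus logical `*_sig`
#'   flags and `n_significant`, the per-row significant count.
#' @export
gof_report <- function(fit, data) {
  stopifnot(inherits(fit, "seg_fit"))
  values <- as_generation_list(data)
  rows <- lapply(names(values), function(gen) {
    e <- pit(values[[gen]], fit$spec, gen)
    n <- length(e)
    u <- uniformity_stats(e)
    nw <- cvm_stat(e)
    dn <- ks_stat(e)
    sig <- c(u > U_CRIT, nw > CVM_CRIT, ks_significant(dn, n, e))
    data.frame(generation = gen, n = n,
               U1sq = u[[1]], U2sq = u[[2]], U3sq = u[[3]],
               nWsq = nw, Dn = dn,
               U1sq_sig = sig[[1]], U2sq_sig = sig[[2]], U3sq_sig = sig[[3]],
               nWsq_sig = sig[[4]], Dn_sig = sig[[5]],
               n_significant = sum(sig))
  })
  out <- do.call(rbind, rows)
  out$model <- fit$model
  class(out) <- c("gof_report", "data.frame")
  out
}

n_significant <- function(report) {
  if (is.null(report)) return(NA_integer_)
  as.integer(sum(report$n_significant))
}

#' Two-stage best-model selection
#'
#' Stage 1 keeps every model within `delta` AIC of the minimum (the literal
#' minimum is always a candidate). Stage 2 picks, among candidates with a
#' goodness-of-fit report, the one with the fewest significant statistics
#' across all generations; ties go to the lower AIC.
#'
#' @param fits named list of `"seg_fit"` objects (one per model).
#' @param reports named list of [gof_report()]s for (at least) the
#'   candidates.
#' @param delta AIC band width for candidacy.
#' @return list with `best` (model code), `candidates`, and `table` (ranking
#'   with AIC, candidacy and significant counts).
#' @export
select_best <- function(fits, reports = NULL, delta = 2) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no successful fits", call. = FALSE)
  codes <- vapply(fits, `[[`, "", "model")
  names(fits) <- codes
  aics <- vapply(fits, `[[`, 0, "aic")
  candidates <- codes[aics <= min(aics) + delta]
  nsig <- vapply(codes, function(cd) {
    if (!is.null(reports) && !is.null(reports[[cd]]))
      n_significant(reports[[cd]]) else NA_integer_
  }, 0L)
  tab <- data.frame(model = codes, aic = aics,
                    candidate = codes %in% candidates,
                    n_significant = nsig, row.names = NULL)
  tab <- tab[order(tab$aic), ]
  cand_tab <- tab[tab$candidate, ]
  scored <- cand_tab[!is.na(cand_tab$n_significant), ]
  best <- if (nrow(scored)) {
    scored$model[order(scored$n_significant, scored$aic)][1L]
  } else {
    cand_tab$model[which.min(cand_tab$aic)]
  }
  list(best = best, candidates = unname(candidates), table = tab)
}
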