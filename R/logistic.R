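# Derived stay-green traits: GLAD from logistic-fitted green leaf-area time
# courses, and VSG from area ratios. The leaf-area course after flowering is
# modeled as y(t) = a / (1 + exp(b + c t)) (a: asymptote cm^2, b: offset,
# c: per-day rate, negative for senescence-delayed decline fitted forward in
# time or positive for decay, depending on the series).

logistic_curve <- function(t, a, b, c) a / (1 + exp(b + c * t))

# numerically safe log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit a logistic curve to a green leaf-area time course
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) for
#' `area = a / (1 + exp(b + c t))`, with self-starting initialization
#' (`a0 = 1.05 * max(area)`; `b`, `c` from the linearization
#' `log(a0 / y - 1) = b + c t` on interior points) and jittered restarts.
#'
#' @param series data frame with columns `t` (days after flowering, strictly
#'   increasing) and `area` (cm^2, >= 0); at least 4 distinct time points.
#' @param init optional named list/vector with starting `a`, `b`, `c`.
#' @param restarts jittered restarts tried beyond the self-start.
#' @return list of class `"logistic_fit"`: `a`, `b`, `c`, `rss`,
#'   `converged`, `identifiable` (FALSE for degenerate, e.g. constant,
#'   series) and `n`.
#' @export
fit_logistic <- function(series, init = NULL, restarts = 5L) {
  stopifnot(is.data.frame(series), all(c("t", "area") %in% names(series)))
  t <- as.numeric(series$t)
  y <- as.numeric(series$area)
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(y < 0) || any(t < 0)) {
    stop("times and areas must be finite and non-negative", call. = FALSE)
  }
  if (length(unique(t)) < 4L) {
    stop("need at least 4 distinct time points for a 3-parameter fit",
         call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    # constant series: a / (1 + exp(b)) = y for any c = 0; non-identifiable
    fit <- list(a = 2 * y[1L], b = 0, c = 0, rss = 0, converged = TRUE,
                identifiable = FALSE, n = length(t))
    class(fit) <- "logistic_fit"
    return(fit)
  }

  self_start <- function() {
    a0 <- 1.05 * max(y)
    interior <- y > 0 & y < a0
    z <- log(a0 / y[interior] - 1)
    lin <- stats::lm.fit(cbind(1, t[interior]), z)
    list(a = a0, b = unname(lin$coefficients[1L]),
         c = unname(lin$coefficients[2L]))
  }
  start <- if (!is.null(init)) as.list(init)[c("a", "b", "c")] else self_start()

  try_fit <- function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ a / (1 + exp(b + c * t)),
        start = st, data = data.frame(t = t, y = y),
        lower = c(a = .Machine$double.eps, b = -Inf, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(fit)
      list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
           rss = sum(stats::resid(fit)^2), converged = TRUE)
    }, error = function(e) NULL)
  }

  best <- try_fit(start)
  if (restarts > 0L) {
    base <- start
    for (j in seq_len(restarts)) {
      jit <- list(a = base$a * stats::runif(1, 0.7, 1.4),
                  b = base$b + stats::rnorm(1, 0, 1),
                  c = base$c * stats::runif(1, 0.5, 2))
      cand <- try_fit(jit)
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
    }
  }
  if (is.null(best)) {
    fit <- list(a = start$a, b = start$b, c = start$c, rss = NA_real_,
                converged = FALSE, identifiable = NA, n = length(t))
    class(fit) <- "logistic_fit"
    return(fit)
  }
  best$identifiable <- abs(best$c) > 1e-8
  best$n <- length(t)
  class(best) <- "logistic_fit"
  best
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> a = %.4g, b = %.4g, c = %.4g; rss = %.4g (n = %d)%s%s\n",
              x$a, x$b, x$c, x$rss, x$n,
              if (isTRUE(x$converged)) "" else " [not converged]",
              if (isFALSE(x$identifiable)) " [non-identifiable]" else ""))
  invisible(x)
}

#' Green leaf area duration (GLAD)
#'
#' The daily mean green leaf area over the `window` days after flowering:
#' `(1/window) * integral_0^window a / (1 + exp(b + c t)) dt`, evaluated by
#' the closed form `a w - (a/c) [softplus(b + c w) - softplus(b)]` (the
#' antiderivative of the logistic), which agrees with adaptive quadrature to
#' high relative accuracy. At `c = 0` the analytic limit `a / (1 + exp(b))`
#' is used.
#'
#' @param fit a `"logistic_fit"` (or any list with `a`, `b`, `c`).
#' @param window integration window in days (> 0), 40 by default.
#' @return the daily mean area (cm^2), with the raw integral (cm^2 day)
#'   attached as attribute `"integral"` and a `"constant_limit"` flag when
#'   `c = 0`.
#' @export
compute_glad <- function(fit, window = 40) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop("logistic fit did not converge", call. = FALSE)
  }
  if (!is.finite(window) || window <= 0) {
    stop("window must be a positive number of days", call. = FALSE)
  }
  a <- fit$a; b <- fit$b; c <- fit$c
  if (c == 0) {
    integral <- a * window / (1 + exp(b))
    out <- integral / window
    attr(out, "integral") <- integral
    attr(out, "constant_limit") <- TRUE
    return(out)
  }
  integral <- a * window - (a / c) * (softplus(b + c * window) - softplus(b))
  out <- integral / window
  attr(out, "integral") <- integral
  attr(out, "constant_limit") <- FALSE
  out
}

#' Visual stay green (VSG)
#'
#' Percent of flowering-stage green leaf area retained at maturity.
#'
#' @param area_maturity green leaf area at maturity (cm^2, >= 0).
#' @param area_flowering green leaf area at flowering (cm^2, > 0).
#' @return `100 * area_maturity / area_flowering`; values above 100 (leaf
#'   area apparently grew after anthesis) are allowed but flagged with a
#'   warning.
#' @export
compute_vsg <- function(area_maturity, area_flowering) {
  if (any(!is.finite(area_flowering)) || any(area_flowering <= 0)) {
    stop("area_flowering must be > 0", call. = FALSE)
  }
  if (any(!is.finite(area_maturity)) || any(area_maturity < 0)) {
    stop("area_maturity must be >= 0", call. = FALSE)
  }
  vsg <- 100 * area_maturity / area_flowering
  if (any(vsg > 100)) {
    warning("VSG above 100%: green leaf area at maturity exceeds flowering",
            call. = FALSE)
  }
  vsg
}

#' Per-individual GLAD from a leaf-area series table
#'
#' Fits each individual's logistic curve and computes GLAD.
#'
#' @param series data frame with columns `individual`, `t`, `area` (as from
#'   [simulate_leaf_area_series()]).
#' @param window integration window in days.
#' @param ... passed to [fit_logistic()].
#' @return data frame with one row per individual: `a`, `b`, `c`, `rss`,
#'   `converged`, `glad`.
#' @export
glad_table <- function(series, window = 40, ...) {
  stopifnot(all(c("individual", "t", "area") %in% names(series)))
  out <- lapply(split(series, series$individual), function(d) {
    fit <- fit_logistic(d[order(d$t), c("t", "area")], ...)
    data.frame(individual = d$individual[1L], a = fit$a, b = fit$b, c = fit$c,
               rss = fit$rss, converged = fit$converged,
               glad = if (isTRUE(fit$converged))
                 as.numeric(compute_glad(fit, window)) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
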