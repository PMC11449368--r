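# Mixture-normal likelihood pieces shared by the EM fitter and the
# goodness-of-fit module.

# log of sum_k w_k N(y | mu_k, v), numerically stable per observation
mixture_logdens <- function(y, means, weights, var) {
  if (var <= 0) stop("variance must be > 0", call. = FALSE)
  L <- outer(y, means, function(yy, mm) {
    -0.5 * log(2 * pi * var) - (yy - mm)^2 / (2 * var)
  })
  L <- sweep(L, 2L, log(weights), "+")
  a <- apply(L, 1L, max)
  a + log(rowSums(exp(L - a)))
}

mixture_cdf <- function(y, means, weights, var) {
  sd <- sqrt(var)
  out <- numeric(length(y))
  for (k in seq_along(means)) {
    out <- out + weights[k] * stats::pnorm(y, means[k], sd)
  }
  out
}

#' Joint log-likelihood of a four-generation sample under a mixture spec
#'
#' P1, P2 and F1 contribute single-normal log-densities; F2 contributes the
#' log of its Mendelian-weighted normal mixture density.
#'
#' @param data a [phenotype_table()] restricted to one trait/population/
#'   environment, or a named list of numeric vectors (`P1`, `P2`, `F1`,
#'   `F2`).
#' @param spec a mixture spec as built by the fitter (component means,
#'   weights and variances per generation).
#' @return the joint log-likelihood (scalar).
#' @export
log_likelihood <- function(data, spec) {
  values <- as_generation_list(data)
  stopifnot(inherits(spec, "mixture_spec"))
  total <- 0
  for (gen in names(values)) {
    g <- spec[[gen]]
    if (is.null(g)) stop("spec lacks generation ", gen, call. = FALSE)
    total <- total + sum(mixture_logdens(values[[gen]], g$means, g$weights, g$var))
  }
  total
}

as_generation_list <- function(data) {
  if (inherits(data, "phenotype_table")) return(generation_values(data))
  if (is.list(data)) {
    bad <- setdiff(names(data), GENERATIONS)
    if (length(bad)) stop("unknown generation(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    return(data[vapply(data, length, 0L) > 0L])
  }
  stop("data must be a phenotype_table or a named list of generation values",
       call. = FALSE)
}

#' Akaike's information criterion
#'
#' @param lnL maximized log-likelihood.
#' @param k number of free parameters.
#' @return `2 * k - 2 * lnL`; lower is better.
#' @export
aic <- function(lnL, k) {
  stopifnot(k >= 0)
  2 * k - 2 * lnL
}
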