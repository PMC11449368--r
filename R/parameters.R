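#' First-order genetic effects by least squares from fitted means
#'
#' Recovers the effect vector as the ordinary least-squares solution of
#' `design_matrix(model) %*% theta = fitted stacked means`. For exactly
#' identified models this reproduces the EM effects bit for bit; it exists
#' as an independent read-out of the mean structure and errors on
#' rank-deficient (confounded) designs.
#'
#' @param fit a `"seg_fit"`.
#' @param model optional `"genetic_model"`; defaults to the fit's model.
#' @return a [genetic_effects()] vector on the full basis.
#' @export
first_order <- function(fit, model = NULL) {
  stopifnot(inherits(fit, "seg_fit"))
  if (!fit$converged) {
    warning("fit did not converge; effects are the best lnL found",
            call. = FALSE)
  }
  model <- if (is.null(model)) as_genetic_model(fit$model)
           else as_genetic_model(model)
  X <- design_matrix(model)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    confounded <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient mean design; confounded effect(s): ",
         paste(confounded, collapse = ", "), call. = FALSE)
  }
  mu <- c(fit$spec$P1$means, fit$spec$P2$means, fit$spec$F1$means,
          fit$spec$F2$means)
  theta <- qr.coef(qrX, mu)
  effects <- drop(model$constraint %*% theta)
  class(effects) <- "genetic_effects"
  effects
}

#' Variance components and heritabilities of the F2
#'
#' Decomposes the F2 phenotypic variance into major-gene, polygene and
#' environmental components: `sigma2_p` is the F2 sample variance (n-1
#' denominator), `sigma2_e` and `sigma2_pg` are the fitted (maximum
#' likelihood) variances, and the major-gene component is the remainder
#' `sigma2_p - sigma2_pg - sigma2_e`, floored at zero. Heritabilities are
#' percentages of `sigma2_p`.
#'
#' @param fit a `"seg_fit"`.
#' @param data the data the model was fitted to (the F2 values set
#'   `sigma2_p`).
#' @return a list of class `"variance_components"` with `sigma2_p`,
#'   `sigma2_mg`, `sigma2_pg`, `sigma2_e`, `h2_mg`, `h2_pg` (percent) and a
#'   `floored` flag.
#' @export
second_order <- function(fit, data) {
  stopifnot(inherits(fit, "seg_fit"))
  values <- as_generation_list(data)
  if (is.null(values$F2)) stop("F2 generation required", call. = FALSE)
  sigma2_p <- stats::var(values$F2)
  if (!is.finite(sigma2_p) || sigma2_p <= 0) {
    stop("F2 phenotypic variance is zero", call. = FALSE)
  }
  sigma2_pg <- fit$sigma2_pg
  sigma2_e <- fit$sigma2_e
  raw_mg <- sigma2_p - sigma2_pg - sigma2_e
  floored <- raw_mg < 0
  if (floored) {
    warning("negative major-gene variance floored at 0 (small-sample artifact)",
            call. = FALSE)
  }
  sigma2_mg <- max(raw_mg, 0)
  out <- list(sigma2_p = sigma2_p, sigma2_mg = sigma2_mg,
              sigma2_pg = sigma2_pg, sigma2_e = sigma2_e,
              h2_mg = heritability(sigma2_mg, sigma2_p),
              h2_pg = heritability(sigma2_pg, sigma2_p),
              floored = floored, model = fit$model)
  class(out) <- "variance_components"
  out
}

#' Heritability of a variance component
#'
#' @param sigma2_component a variance component (>= 0).
#' @param sigma2_p the F2 phenotypic variance (> 0).
#' @return `100 * sigma2_component / sigma2_p`, in percent.
#' @export
heritability <- function(sigma2_component, sigma2_p) {
  stopifnot(all(sigma2_p > 0), all(sigma2_component >= 0))
  100 * sigma2_component / sigma2_p
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components %s> sigma2_p = %.4g = mg %.4g + pg %.4g + e %.4g%s\n",
    x$model, x$sigma2_p, x$sigma2_mg, x$sigma2_pg, x$sigma2_e,
    if (x$floored) " [floored]" else ""))
  cat(sprintf("  h2_mg = %.2f%%, h2_pg = %.2f%%\n", x$h2_mg, x$h2_pg))
  invisible(x)
}
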