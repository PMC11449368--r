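# Generation-wise mean structure. Every generation/component mean is a linear
# combination of the full effect basis; rows below are those coefficient
# vectors. F2 segregates the major genotypes in Mendelian ratios; the pooled
# polygenic background contributes its expectation per generation
# (P1/P2: +-[d] + [i]; F1: [h] + [l]; F2: [h]/2 + [l]/4 — heterozygosity 1/2
# and vanishing expected additive deviation in F2).

basis_row <- function(...) {
  row <- stats::setNames(numeric(length(effect_basis())), effect_basis())
  v <- c(...)
  if (length(v)) row[names(v)] <- v
  row
}

# genotype coefficient rows + Mendelian weights (numerators over weight_den)
major_genotypes <- function(n_major) {
  if (n_major == 2L) {
    rows <- rbind(
      AABB = basis_row(m = 1, da =  1, db =  1, i =  1),
      AABb = basis_row(m = 1, da =  1, hb =  1, jab =  1),
      AAbb = basis_row(m = 1, da =  1, db = -1, i = -1),
      AaBB = basis_row(m = 1, ha =  1, db =  1, jba =  1),
      AaBb = basis_row(m = 1, ha =  1, hb =  1, l =  1),
      Aabb = basis_row(m = 1, ha =  1, db = -1, jba = -1),
      aaBB = basis_row(m = 1, da = -1, db =  1, i = -1),
      aaBb = basis_row(m = 1, da = -1, hb =  1, jab = -1),
      aabb = basis_row(m = 1, da = -1, db = -1, i =  1)
    )
    list(rows = rows, weight_num = c(1, 2, 1, 2, 4, 2, 1, 2, 1),
         weight_den = 16, high = "AABB", low = "aabb", het = "AaBb")
  } else if (n_major == 1L) {
    rows <- rbind(
      AA = basis_row(m = 1, da =  1),
      Aa = basis_row(m = 1, ha =  1),
      aa = basis_row(m = 1, da = -1)
    )
    list(rows = rows, weight_num = c(1, 2, 1), weight_den = 4,
         high = "AA", low = "aa", het = "Aa")
  } else {
    rows <- rbind(G = basis_row(m = 1))
    list(rows = rows, weight_num = 1, weight_den = 1,
         high = "G", low = "G", het = "G")
  }
}

# Full structural description of a model: P1/P2/F1 coefficient rows and the
# merged F2 component rows with exact Mendelian weights. Components whose
# projected rows (row %*% C) coincide are merged with summed weights —
# symbolic equality of the mean expressions, independent of effect values.
model_structure <- function(model) {
  g <- major_genotypes(model$n_major_genes)
  poly_f2 <- basis_row(h_poly = 0.5, l_poly = 0.25)
  f2_rows <- sweep(g$rows, 2L, poly_f2, FUN = "+")  # polygenic F2 expectation
  p1 <- g$rows[g$high, ] + basis_row(d_poly = 1, i_poly = 1)
  p2 <- g$rows[g$low, ] + basis_row(d_poly = -1, i_poly = 1)
  f1 <- g$rows[g$het, ] + basis_row(h_poly = 1, l_poly = 1)

  proj <- f2_rows %*% model$constraint
  key <- apply(proj, 1L, paste, collapse = "|")
  groups <- split(seq_len(nrow(f2_rows)), factor(key, levels = unique(key)))
  merged_rows <- t(vapply(groups, function(idx) f2_rows[idx[1L], ],
                          numeric(ncol(f2_rows))))
  rownames(merged_rows) <- vapply(groups, function(idx)
    paste(rownames(f2_rows)[idx], collapse = "+"), "")
  merged_num <- vapply(groups, function(idx) sum(g$weight_num[idx]), 0)
  names(merged_num) <- rownames(merged_rows)

  list(P1 = p1, P2 = p2, F1 = f1,
       f2 = list(rows = merged_rows, weight_num = merged_num),
       weight_den = g$weight_den)
}

check_effects <- function(model, effects) {
  effects <- as_genetic_effects(effects)
  theta <- unclass(effects)[model$free_params]
  implied <- drop(model$constraint %*% theta)
  bad <- names(implied)[abs(implied - unclass(effects)) > 1e-12]
  if (length(bad)) {
    stop(sprintf("effects violate the structural constraints of %s (%s)",
                 model$code, paste(bad, collapse = ", ")), call. = FALSE)
  }
  theta
}

#' Generation-wise component means and Mendelian weights
#'
#' Evaluates a model's mean structure at a vector of genetic effects: single
#' means for P1, P2 and F1, and the Mendelian mixture of major-genotype
#' components for F2. F2 components whose mean expressions coincide under the
#' model's constraints (e.g. the binomial collapse of `2MG-EA`) are merged
#' with summed weights, which remain exactly Mendelian fractions.
#'
#' @param model a `"genetic_model"` or a model code.
#' @param effects a [genetic_effects()] vector respecting the model's
#'   structural zeros and ties (violations are an error, not silently fixed).
#' @return a list of class `"mixture_means"` with elements `P1`, `P2`, `F1`
#'   (scalars) and `F2` (data frame of component `mean` and `weight`).
#' @examples
#' genotype_means("2MG-EA", genetic_effects(da = 1, db = 1))$F2
#' @export
genotype_means <- function(model, effects) {
  model <- as_genetic_model(model)
  theta <- check_effects(model, effects)
  spec <- model_structure(model)
  X <- design_matrix(model)
  mu <- drop(X %*% theta)
  mu_f2 <- unname(mu[-(1:3)])
  # beyond the structural merge, components whose means coincide exactly at
  # these effect values (e.g. everything collapses to m at zero effects) are
  # merged with summed (still exactly Mendelian) weights
  grp <- match(mu_f2, mu_f2)
  groups <- split(seq_along(mu_f2), factor(grp, levels = unique(grp)))
  comp_names <- rownames(spec$f2$rows)
  out <- list(
    P1 = unname(mu["P1"]), P2 = unname(mu["P2"]), F1 = unname(mu["F1"]),
    F2 = data.frame(
      component = vapply(groups, function(idx)
        paste(comp_names[idx], collapse = "+"), ""),
      mean = mu_f2[vapply(groups, `[[`, 0L, 1L)],
      weight = vapply(groups, function(idx)
        sum(spec$f2$weight_num[idx]), 0) / spec$weight_den,
      row.names = NULL
    ),
    model = model$code
  )
  class(out) <- "mixture_means"
  out
}

#' Design matrix of a genetic model
#'
#' The linear map from a model's free effect parameters to the stacked
#' generation means (P1, P2, F1, then the merged F2 components):
#' `genotype_means(model, effects)` equals `design_matrix(model) %*% theta`
#' for every admissible effect vector. The F2 component Mendelian weights are
#' attached as attribute `"f2_weights"`.
#'
#' @inheritParams genotype_means
#' @return a numeric matrix with one row per generation/component mean and one
#'   column per free parameter.
#' @export
design_matrix <- function(model) {
  model <- as_genetic_model(model)
  spec <- model_structure(model)
  R <- rbind(P1 = spec$P1, P2 = spec$P2, F1 = spec$F1, spec$f2$rows)
  rownames(R)[-(1:3)] <- paste0("F2:", rownames(spec$f2$rows))
  X <- R %*% model$constraint
  attr(X, "f2_weights") <- spec$f2$weight_num / spec$weight_den
  X
}

# MixtureSpec: per-generation component means, weights and variances.
# P1/P2/F1 are single normals with variance sigma2_e; the polygenic variance
# segregates only in F2, inflating each F2 component to sigma2_e + sigma2_pg.
mixture_spec <- function(model, effects, sigma2_e, sigma2_pg = 0) {
  model <- as_genetic_model(model)
  if (!is.finite(sigma2_e) || sigma2_e <= 0) stop("sigma2_e must be > 0", call. = FALSE)
  if (!is.finite(sigma2_pg) || sigma2_pg < 0) stop("sigma2_pg must be >= 0", call. = FALSE)
  if (sigma2_pg > 0 && !model$has_sigma2_pg) {
    stop(sprintf("model %s has no polygenic variance component", model$code),
         call. = FALSE)
  }
  mu <- genotype_means(model, effects)
  spec <- list(
    P1 = list(means = mu$P1, weights = 1, var = sigma2_e),
    P2 = list(means = mu$P2, weights = 1, var = sigma2_e),
    F1 = list(means = mu$F1, weights = 1, var = sigma2_e),
    F2 = list(means = mu$F2$mean, weights = mu$F2$weight,
              var = sigma2_e + sigma2_pg),
    model = model$code, sigma2_e = sigma2_e, sigma2_pg = sigma2_pg
  )
  class(spec) <- "mixture_spec"
  spec
}

#' @export
print.mixture_means <- function(x, ...) {
  cat(sprintf("<mixture_means %s> P1 %.4g, P2 %.4g, F1 %.4g; F2 %d component(s)\n",
              x$model, x$P1, x$P2, x$F1, nrow(x$F2)))
  print(x$F2, ...)
  invisible(x)
}
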