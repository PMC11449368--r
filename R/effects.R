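#' Genetic effect vectors
#'
#' The full effect basis of the two-locus major-gene plus polygene
#' parameterization used throughout the package:
#'
#' * `m` — population mean baseline (trait units);
#' * `da`, `db` — additive effects of the first and second major gene
#'   (half the difference between the two homozygotes at that locus);
#' * `ha`, `hb` — dominance effects (heterozygote deviation from the
#'   homozygote midpoint);
#' * `i`, `jab`, `jba`, `l` — additive×additive, additive×dominance,
#'   dominance×additive and dominance×dominance epistasis between the two
#'   major loci;
#' * `d_poly`, `h_poly` — pooled additive `[d]` and dominance `[h]` effects
#'   of the polygenic background;
#' * `i_poly`, `l_poly` — pooled polygenic additive×additive `[i]` and
#'   dominance×dominance `[l]` epistasis (used only by the `*-ADI`
#'   polygene models).
#'
#' Effects a model does not use are structurally zero: [genotype_means()]
#' and the EM fitter refuse effect vectors that violate a model's
#' constraints rather than silently ignoring entries.
#'
#' @param ... named effect values; unnamed effects default to 0.
#' @return a named numeric vector over the full 13-effect basis, of class
#'   `"genetic_effects"`.
#' @examples
#' genetic_effects(m = 30, da = 28.28, db = 17.95, d_poly = -18.34, h_poly = 42.74)
#' @export
genetic_effects <- function(...) {
  supplied <- c(...)
  eff <- stats::setNames(numeric(length(effect_basis())), effect_basis())
  if (length(supplied)) {
    if (is.null(names(supplied)) || any(names(supplied) == "")) {
      stop("all effects must be named", call. = FALSE)
    }
    unknown <- setdiff(names(supplied), effect_basis())
    if (length(unknown)) {
      stop("unknown effect name(s): ", paste(unknown, collapse = ", "),
           "; valid names are ", paste(effect_basis(), collapse = ", "),
           call. = FALSE)
    }
    if (!all(is.finite(supplied))) stop("effects must be finite", call. = FALSE)
    eff[names(supplied)] <- supplied
  }
  class(eff) <- "genetic_effects"
  eff
}

#' @rdname genetic_effects
#' @export
effect_basis <- function() {
  c("m", "da", "db", "ha", "hb", "i", "jab", "jba", "l",
    "d_poly", "h_poly", "i_poly", "l_poly")
}

as_genetic_effects <- function(x) {
  if (inherits(x, "genetic_effects")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(do.call(genetic_effects, as.list(x)))
  stop("cannot interpret object as genetic effects", call. = FALSE)
}

#' @export
print.genetic_effects <- function(x, ...) {
  nz <- x[x != 0]
  cat("<genetic_effects>")
  if (!length(nz)) {
    cat(" all zero\n")
  } else {
    cat("\n")
    print(unclass(nz), ...)
  }
  invisible(x)
}
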