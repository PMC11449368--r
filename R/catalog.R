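# Model catalog: each inheritance model is a set of linear constraints on the
# full effect basis. A model's constraint matrix C (basis x free) maps its free
# parameters to the basis, so that every generation/component mean is linear in
# the free parameters (design_matrix) and structural ties (e.g. da = db under
# equal-additive models) hold exactly by construction.

# Declarative catalog table. `free`: free effect names; `ties`: named list
# mapping a constrained basis effect to a linear expression c(name = coef) in
# free effects. Everything else is structurally zero.
catalog_table <- function() {
  list(
    # --- one major gene -----------------------------------------------------
    list(code = "1MG-AD",  n_major = 1L, poly = "none",
         free = c("m", "da", "ha"), ties = list()),
    list(code = "1MG-A",   n_major = 1L, poly = "none",
         free = c("m", "da"), ties = list()),
    list(code = "1MG-EAD", n_major = 1L, poly = "none",
         free = c("m", "da"), ties = list(ha = c(da = 1))),
    list(code = "1MG-NCD", n_major = 1L, poly = "none",
         free = c("m", "da"), ties = list(ha = c(da = -1))),
    # --- two major genes ----------------------------------------------------
    list(code = "2MG-ADI", n_major = 2L, poly = "none",
         free = c("m", "da", "db", "ha", "hb", "i", "jab", "jba", "l"),
         ties = list()),
    list(code = "2MG-AD",  n_major = 2L, poly = "none",
         free = c("m", "da", "db", "ha", "hb"), ties = list()),
    list(code = "2MG-A",   n_major = 2L, poly = "none",
         free = c("m", "da", "db"), ties = list()),
    list(code = "2MG-EA",  n_major = 2L, poly = "none",
         free = c("m", "da"), ties = list(db = c(da = 1))),
    list(code = "2MG-CD",  n_major = 2L, poly = "none",
         free = c("m", "da", "db"),
         ties = list(ha = c(da = 1), hb = c(db = 1))),
    list(code = "2MG-EAD", n_major = 2L, poly = "none",
         free = c("m", "da"),
         ties = list(db = c(da = 1), ha = c(da = 1), hb = c(da = 1))),
    # --- no major gene ------------------------------------------------------
    list(code = "0MG",     n_major = 0L, poly = "none",
         free = "m", ties = list()),
    list(code = "PG-AD",   n_major = 0L, poly = "AD",
         free = c("m", "d_poly", "h_poly"), ties = list()),
    list(code = "PG-ADI",  n_major = 0L, poly = "ADI",
         free = c("m", "d_poly", "h_poly", "i_poly", "l_poly"), ties = list()),
    # --- one major gene + polygenes -----------------------------------------
    list(code = "MX1-AD-AD",  n_major = 1L, poly = "AD",
         free = c("m", "da", "ha", "d_poly", "h_poly"), ties = list()),
    list(code = "MX1-AD-ADI", n_major = 1L, poly = "ADI",
         free = c("m", "da", "ha", "d_poly", "h_poly", "i_poly", "l_poly"),
         ties = list()),
    list(code = "MX1-A-AD",   n_major = 1L, poly = "AD",
         free = c("m", "da", "d_poly", "h_poly"), ties = list()),
    list(code = "MX1-EAD-AD", n_major = 1L, poly = "AD",
         free = c("m", "da", "d_poly", "h_poly"), ties = list(ha = c(da = 1))),
    # --- two major genes + polygenes ----------------------------------------
    list(code = "MX2-ADI-AD",  n_major = 2L, poly = "AD",
         free = c("m", "da", "db", "ha", "hb", "i", "jab", "jba", "l",
                  "d_poly", "h_poly"),
         ties = list()),
    list(code = "MX2-ADI-ADI", n_major = 2L, poly = "ADI",
         free = c("m", "da", "db", "ha", "hb", "i", "jab", "jba", "l",
                  "d_poly", "h_poly", "i_poly", "l_poly"),
         ties = list()),
    list(code = "MX2-AD-AD",   n_major = 2L, poly = "AD",
         free = c("m", "da", "db", "ha", "hb", "d_poly", "h_poly"),
         ties = list()),
    list(code = "MX2-A-AD",    n_major = 2L, poly = "AD",
         free = c("m", "da", "db", "d_poly", "h_poly"), ties = list()),
    list(code = "MX2-EA-AD",   n_major = 2L, poly = "AD",
         free = c("m", "da", "d_poly", "h_poly"), ties = list(db = c(da = 1))),
    list(code = "MX2-CD-AD",   n_major = 2L, poly = "AD",
         free = c("m", "da", "db", "d_poly", "h_poly"),
         ties = list(ha = c(da = 1), hb = c(db = 1))),
    list(code = "MX2-EAD-AD",  n_major = 2L, poly = "AD",
         free = c("m", "da", "d_poly", "h_poly"),
         ties = list(db = c(da = 1), ha = c(da = 1), hb = c(da = 1)))
  )
}

build_model <- function(def) {
  basis <- effect_basis()
  C <- matrix(0, nrow = length(basis), ncol = length(def$free),
              dimnames = list(basis, def$free))
  for (f in def$free) C[f, f] <- 1
  for (eff in names(def$ties)) {
    expr <- def$ties[[eff]]
    C[eff, names(expr)] <- expr
  }
  has_pg <- def$poly != "none"
  model <- list(
    code = def$code,
    n_major_genes = def$n_major,
    polygene_class = def$poly,
    free_params = def$free,
    constraint = C,
    has_sigma2_pg = has_pg,
    k = length(def$free) + 1L + as.integer(has_pg)
  )
  class(model) <- "genetic_model"
  model
}

#' Catalog of major-gene plus polygene inheritance models
#'
#' Returns the catalog of 24 inheritance models fitted jointly to the P1, P2,
#' F1 and F2 generations: one- and two-major-gene models (`1MG-*`, `2MG-*`),
#' polygene-only models (`PG-*`), the no-genetic-effect null (`0MG`), and
#' mixed major-gene plus polygene models (`MX1-*`, `MX2-*`). Code suffixes
#' describe the major-gene effect class (A additive, D dominance, I
#' epistasis, E equal additive effects, CD complete dominance) and, after the
#' second dash, the polygene class (AD or ADI).
#'
#' @param subset optional character vector of model codes; the default returns
#'   the full catalog.
#' @return a named list of `"genetic_model"` objects. Each carries its code,
#'   number of major genes, polygene class, free parameter names, the
#'   constraint matrix mapping free parameters to the full effect basis, and
#'   the parameter count `k` used for AIC (free mean parameters + 1
#'   environmental variance + 1 polygenic variance when present).
#' @examples
#' length(model_catalog())                  # 24
#' model_catalog("2MG-EA")[["2MG-EA"]]$free_params   # m, da (db tied to da)
#' @export
model_catalog <- function(subset = NULL) {
  defs <- catalog_table()
  models <- lapply(defs, build_model)
  names(models) <- vapply(models, `[[`, "", "code")
  if (is.null(subset)) return(models)
  if (!length(subset)) {
    stop("empty model subset; valid codes: ",
         paste(names(models), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(subset, names(models))
  if (length(unknown)) {
    stop("unknown model code(s): ", paste(unknown, collapse = ", "),
         "; valid codes: ", paste(names(models), collapse = ", "),
         call. = FALSE)
  }
  models[subset]
}

as_genetic_model <- function(model) {
  if (inherits(model, "genetic_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    return(model_catalog(model)[[1L]])
  }
  stop("expected a genetic_model or a model code", call. = FALSE)
}

#' @export
print.genetic_model <- function(x, ...) {
  cat(sprintf("<genetic_model %s> %d major gene(s), polygenes: %s\n",
              x$code, x$n_major_genes, x$polygene_class))
  cat("  free:", paste(x$free_params, collapse = ", "),
      sprintf(" (k = %d)\n", x$k))
  invisible(x)
}

#' Export the model catalog as JSON
#'
#' Serializes every model's code, free parameters, F2 mixture weights and
#' component mean formulas (as strings over the effect basis) for
#' documentation or cross-language validation.
#'
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
catalog_json <- function(path = NULL) {
  models <- model_catalog()
  out <- lapply(models, function(model) {
    spec <- model_structure(model)
    formula_of <- function(row) {
      nz <- row[row != 0]
      if (!length(nz)) return("0")
      paste(sprintf("%+g*%s", nz, names(nz)), collapse = " ")
    }
    list(
      code = model$code,
      n_major_genes = model$n_major_genes,
      polygene_class = model$polygene_class,
      free_params = model$free_params,
      k = model$k,
      f2_weights = spec$f2$weight_num / spec$weight_den,
      means = list(
        P1 = formula_of(spec$P1), P2 = formula_of(spec$P2),
        F1 = formula_of(spec$F1),
        F2 = apply(spec$f2$rows, 1L, formula_of)
      )
    )
  })
  json <- jsonlite::toJSON(unname(out), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
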