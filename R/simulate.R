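#' Simulation scenarios for four-generation populations
#'
#' A scenario bundles everything needed to generate a synthetic P1/P2/F1/F2
#' dataset with the exact statistical structure the segregation analysis
#' assumes: an inheritance model, its effect values, the environmental and
#' polygenic variances, per-generation sample sizes and a seed.
#'
#' @param name scenario label (also used as default population label).
#' @param model a model code or `"genetic_model"`.
#' @param effects a [genetic_effects()] vector respecting the model's
#'   constraints.
#' @param sigma2_e environmental variance (> 0, trait units squared).
#' @param sigma2_pg polygenic variance (>= 0; only mixed/polygene models may
#'   have a positive value).
#' @param n named integer vector of per-generation sample sizes; `F2 >= 30`.
#' @param seed integer seed for reproducible simulation.
#' @param trait,environment labels written into the simulated table.
#' @return an object of class `"scenario"`.
#' @export
scenario <- function(name, model, effects, sigma2_e, sigma2_pg = 0,
                     n = c(P1 = 3, P2 = 3, F1 = 3, F2 = 200), seed = NULL,
                     trait = "trait", environment = "E1") {
  model <- as_genetic_model(model)
  effects <- as_genetic_effects(effects)
  check_effects(model, effects)
  if (!is.finite(sigma2_e) || sigma2_e <= 0) stop("sigma2_e must be > 0", call. = FALSE)
  if (!is.finite(sigma2_pg) || sigma2_pg < 0) stop("sigma2_pg must be >= 0", call. = FALSE)
  missing_gen <- setdiff(GENERATIONS, names(n))
  if (length(missing_gen)) {
    stop("n must name all generations; missing: ",
         paste(missing_gen, collapse = ", "), call. = FALSE)
  }
  n <- vapply(n[GENERATIONS], as.integer, 0L)
  if (n["F2"] < 30L) stop("n[F2] must be >= 30", call. = FALSE)
  if (any(n < 1L)) stop("all generation sizes must be >= 1", call. = FALSE)
  out <- list(name = name, model = model, effects = effects,
              sigma2_e = sigma2_e, sigma2_pg = sigma2_pg, n = n,
              seed = seed, trait = trait, environment = environment)
  class(out) <- "scenario"
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> model %s; n = %s; sigma2_e = %.4g, sigma2_pg = %.4g\n",
              x$name, x$model$code,
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = " "),
              x$sigma2_e, x$sigma2_pg))
  invisible(x)
}

#' Simulate a four-generation phenotype dataset
#'
#' P1, P2 and F1 are drawn from their single normals (environmental variance
#' only); each F2 plant first draws a major genotype from the Mendelian
#' component weights and then a phenotype around that component mean with
#' variance `sigma2_e + sigma2_pg`.
#'
#' @param sc a [scenario()].
#' @param n optional named vector overriding the scenario's sample sizes.
#' @param seed optional seed overriding the scenario's.
#' @return a [phenotype_table()]; the generating component index of each F2
#'   plant is attached as attribute `"f2_component"`.
#' @export
simulate_population <- function(sc, n = NULL, seed = NULL) {
  stopifnot(inherits(sc, "scenario"))
  sizes <- sc$n
  if (!is.null(n)) sizes[names(n)] <- as.integer(n)
  if (sizes["F2"] < 30L) stop("n[F2] must be >= 30", call. = FALSE)
  if (is.null(seed)) seed <- sc$seed
  spec <- mixture_spec(sc$model, sc$effects, sc$sigma2_e,
                       if (sc$model$has_sigma2_pg) sc$sigma2_pg else 0)
  with_private_seed(seed, {
    draws <- list()
    for (gen in c("P1", "P2", "F1")) {
      draws[[gen]] <- stats::rnorm(sizes[gen], spec[[gen]]$means,
                                   sqrt(spec[[gen]]$var))
    }
    K <- length(spec$F2$means)
    comp <- sample.int(K, sizes["F2"], replace = TRUE, prob = spec$F2$weights)
    draws$F2 <- stats::rnorm(sizes["F2"], spec$F2$means[comp],
                             sqrt(spec$F2$var))
    records <- do.call(rbind, lapply(GENERATIONS, function(gen) {
      data.frame(population = sc$name, environment = sc$environment,
                 generation = gen,
                 individual = sprintf("%s_%03d", gen, seq_len(sizes[gen])),
                 trait = sc$trait, value = draws[[gen]])
    }))
    out <- phenotype_table(records)
    attr(out, "f2_component") <- comp
    out
  })
}

#' Load the published summary statistics, effect estimates and variance
#' components of the maize stay-green study populations
#'
#' Per-trait, per-environment reported estimates for the TMF2 and TXF2
#' crosses (common stay-green parent T01 crossed to Mo17 and Xin3): parent
#' and F2 summary statistics, best-model first-order effects, and
#' second-order variance components. These tables parameterize
#' [scenario_bank()]; the raw field phenotypes themselves were never
#' deposited, which is why the generator exists.
#'
#' @return a data frame.
#' @export
study_summary_stats <- function() {
  utils::read.csv(system.file("extdata", "study_summary_stats.csv",
                              package = "segmix"))
}

#' @rdname study_summary_stats
#' @export
study_effects <- function() {
  utils::read.csv(system.file("extdata", "study_effects.csv",
                              package = "segmix"))
}

#' @rdname study_summary_stats
#' @export
study_variance_components <- function() {
  utils::read.csv(system.file("extdata", "study_variance_components.csv",
                              package = "segmix"))
}

#' Bank of simulation scenarios
#'
#' One scenario per reported best-model row of the study (population x trait
#' x environment), parameterized by the published first-order effects and
#' variance components:
#' * the baseline `m` is anchored so the model's P1 mean reproduces the
#'   reported P1 mean (`m` itself is never reported);
#' * `sigma2_e` is the reported F2 phenotypic variance minus the reported
#'   major-gene and polygene variances, floored at 1% of the phenotypic
#'   variance where the published components leave no room for it;
#' * F2 sample size follows the field design (200 plants in E1, 400 in E2);
#'   parent and F1 generations default to triplicates.
#'
#' Three edge-case scenarios are appended: `null` (no genetic effects),
#' `one_gene` (a clean single-gene additive-dominance architecture) and
#' `variance_dominated` (major-gene effects buried in environmental noise).
#'
#' @param n_parents sample size for each of P1, P2 and F1 (triplicates are
#'   fragile for goodness-of-fit testing; raise as needed).
#' @param seed base seed; scenario `i` gets `seed + i`.
#' @return named list of [scenario()] objects.
#' @export
scenario_bank <- function(n_parents = 3L, seed = 20260L) {
  eff_tab <- study_effects()
  var_tab <- study_variance_components()
  sum_tab <- study_summary_stats()
  bank <- list()
  for (r in seq_len(nrow(eff_tab))) {
    row <- eff_tab[r, ]
    model <- as_genetic_model(row$model)
    vrow <- var_tab[var_tab$population == row$population &
                      var_tab$trait == row$trait &
                      var_tab$environment == row$environment, ]
    srow <- sum_tab[sum_tab$population == row$population &
                      sum_tab$trait == row$trait &
                      sum_tab$environment == row$environment, ]
    theta <- stats::setNames(numeric(length(model$free_params)),
                             model$free_params)
    for (nm in setdiff(model$free_params, "m")) {
      v <- row[[nm]]
      theta[nm] <- if (is.null(v) || is.na(v)) 0 else v
    }
    # anchor m so the P1 mean matches the reported value
    x_p1 <- design_matrix(model)["P1", ]
    theta["m"] <- (srow$p1_mean - sum(x_p1 * theta)) / x_p1["m"]
    effects <- drop(model$constraint %*% theta)
    class(effects) <- "genetic_effects"
    sigma2_p <- srow$f2_sd^2
    sigma2_pg <- if (model$has_sigma2_pg && !is.na(vrow$sigma2_pg))
      vrow$sigma2_pg else 0
    sigma2_e <- max(sigma2_p - vrow$sigma2_mg - sigma2_pg, 0.01 * sigma2_p)
    n_f2 <- if (row$environment == "E2") 400L else 200L
    name <- sprintf("%s_%s_%s", row$population, row$trait, row$environment)
    bank[[name]] <- scenario(
      name, model, effects, sigma2_e, sigma2_pg,
      n = c(P1 = n_parents, P2 = n_parents, F1 = n_parents, F2 = n_f2),
      seed = seed + r, trait = row$trait, environment = row$environment)
  }
  n_edge <- c(P1 = n_parents, P2 = n_parents, F1 = n_parents, F2 = 200L)
  bank$null <- scenario("null", "0MG", genetic_effects(m = 50),
                        sigma2_e = 25, n = n_edge,
                        seed = seed + nrow(eff_tab) + 1L)
  bank$one_gene <- scenario("one_gene", "1MG-AD",
                            genetic_effects(m = 0, da = 10, ha = 5),
                            sigma2_e = 4, n = n_edge,
                            seed = seed + nrow(eff_tab) + 2L)
  bank$variance_dominated <- scenario(
    "variance_dominated", "2MG-A",
    genetic_effects(m = 50, da = 1, db = 0.5),
    sigma2_e = 25, n = n_edge, seed = seed + nrow(eff_tab) + 3L)
  bank
}

#' Simulate per-plant green leaf-area time courses
#'
#' Each individual's logistic parameters `(a, b, c)` are jittered around the
#' supplied truth (multiplicative Gaussian jitter), then Gaussian observation
#' noise is added to the curve `a / (1 + exp(b + c t))` at the requested
#' days after flowering.
#'
#' @param a,b,c logistic parameters (asymptote cm^2, offset, rate per day).
#' @param noise_sd observation noise SD (cm^2).
#' @param times days after flowering (>= 0).
#' @param n_individuals number of plants.
#' @param seed integer seed.
#' @param jitter_frac SD of the multiplicative parameter jitter.
#' @return data frame with columns `individual`, `t`, `area` and attribute
#'   `"truth"` (per-individual generating parameters).
#' @export
simulate_leaf_area_series <- function(a, b, c, noise_sd = 0,
                                      times = seq(0, 40, by = 5),
                                      n_individuals = 1L, seed = NULL,
                                      jitter_frac = 0.05) {
  stopifnot(a > 0, length(times) >= 1L, all(times >= 0))
  with_private_seed(seed, {
    truth <- data.frame(
      individual = sprintf("ind_%03d", seq_len(n_individuals)),
      a = a * stats::rnorm(n_individuals, 1, jitter_frac),
      b = b * stats::rnorm(n_individuals, 1, jitter_frac),
      c = c * stats::rnorm(n_individuals, 1, jitter_frac)
    )
    out <- do.call(rbind, lapply(seq_len(n_individuals), function(ind) {
      mu <- truth$a[ind] / (1 + exp(truth$b[ind] + truth$c[ind] * times))
      data.frame(individual = truth$individual[ind], t = times,
                 area = pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0))
    }))
    attr(out, "truth") <- truth
    out
  })
}
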