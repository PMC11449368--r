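#' Full segregation-analysis pipeline
#'
#' For every (population, environment, trait) stratum of the input, computes
#' per-generation descriptive statistics, fits the requested model catalog,
#' runs goodness-of-fit tests for the AIC candidates, selects the best model
#' and estimates its first- and second-order genetic parameters. Analyses
#' are stratified: no cross-environment model is fitted.
#'
#' @param data a [phenotype_table()] or a CSV path readable by
#'   [read_phenotypes()].
#' @param traits optional trait subset (default: all present).
#' @param models character vector of model codes (default: full catalog).
#' @param delta AIC candidacy band for [select_best()].
#' @param seed integer seed; stratum `i` fits with seed `seed + i`, making
#'   the whole bundle deterministic.
#' @param options [em_options()] shared by every fit (its seed is overridden
#'   per stratum).
#' @param verbose log one line per (trait, model) fit.
#' @return a list of class `"report_bundle"`: `descriptive`, `aic`
#'   (model x stratum AIC long table), `fitness`, `params` (first- and
#'   second-order tables), `selection`, `failures`, and `provenance`.
#' @export
run_pipeline <- function(data, traits = NULL, models = NULL, delta = 2,
                         seed = 1L, options = em_options(), verbose = FALSE) {
  if (is.character(data) && length(data) == 1L) data <- read_phenotypes(data)
  stopifnot(inherits(data, "phenotype_table"))
  if (is.null(models)) models <- names(model_catalog())
  catalog <- model_catalog(models)
  if (is.null(traits)) traits <- unique(data$trait)

  strata <- unique(data[data$trait %in% traits,
                        c("population", "environment", "trait")])
  if (!nrow(strata)) stop("no records for the requested traits", call. = FALSE)
  rownames(strata) <- NULL

  descriptive <- list(); aic_rows <- list(); fitness <- list()
  first_rows <- list(); second_rows <- list(); selection <- list()
  failures <- list()

  for (s in seq_len(nrow(strata))) {
    pop <- strata$population[s]; env <- strata$environment[s]
    tr <- strata$trait[s]
    id <- sprintf("%s/%s/%s", pop, env, tr)
    values <- generation_values(data, trait = tr, population = pop,
                                environment = env)

    desc <- do.call(rbind, lapply(names(values), function(gen) {
      cbind(population = pop, environment = env, trait = tr,
            generation = gen, trait_summary(values[[gen]]))
    }))
    descriptive[[id]] <- desc

    opts <- options
    opts$seed <- seed + s
    opts$verbose <- verbose
    fits <- list()
    for (code in names(catalog)) {
      fits[[code]] <- tryCatch(
        em_fit(values, catalog[[code]], opts),
        error = function(e) {
          failures[[length(failures) + 1L]] <<- data.frame(
            population = pop, environment = env, trait = tr, model = code,
            error = conditionMessage(e))
          NULL
        })
    }
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) {
      failures[[length(failures) + 1L]] <- data.frame(
        population = pop, environment = env, trait = tr, model = NA,
        error = "all models failed")
      next
    }
    aic_rows[[id]] <- data.frame(
      population = pop, environment = env, trait = tr,
      model = vapply(fits, `[[`, "", "model"),
      lnL = vapply(fits, `[[`, 0, "lnL"),
      k = vapply(fits, `[[`, 0L, "k"),
      aic = vapply(fits, `[[`, 0, "aic"),
      converged = vapply(fits, `[[`, TRUE, "converged"),
      n_iter = vapply(fits, `[[`, 0L, "n_iter"), row.names = NULL)

    aics <- vapply(fits, `[[`, 0, "aic")
    cand <- names(fits)[aics <= min(aics) + delta]
    reports <- lapply(fits[cand], gof_report, data = values)
    sel <- select_best(fits, reports, delta = delta)
    selection[[id]] <- data.frame(population = pop, environment = env,
                                  trait = tr, best = sel$best,
                                  candidates = paste(sel$candidates,
                                                     collapse = ";"))
    fitness[[id]] <- do.call(rbind, lapply(names(reports), function(code) {
      cbind(population = pop, environment = env, trait = tr,
            as.data.frame(reports[[code]]))
    }))

    best_fit <- fits[[sel$best]]
    eff <- tryCatch(first_order(best_fit), error = function(e) best_fit$effects)
    first_rows[[id]] <- cbind(
      data.frame(population = pop, environment = env, trait = tr,
                 model = sel$best),
      as.data.frame(as.list(unclass(eff))))
    vc <- second_order(best_fit, values)
    second_rows[[id]] <- data.frame(
      population = pop, environment = env, trait = tr, model = sel$best,
      sigma2_p = vc$sigma2_p, sigma2_mg = vc$sigma2_mg,
      sigma2_pg = vc$sigma2_pg, sigma2_e = vc$sigma2_e,
      h2_mg = vc$h2_mg, h2_pg = vc$h2_pg)
  }

  bundle <- list(
    descriptive = do.call(rbind, c(descriptive, list(make.row.names = FALSE))),
    aic = do.call(rbind, c(aic_rows, list(make.row.names = FALSE))),
    fitness = if (length(fitness))
      do.call(rbind, c(fitness, list(make.row.names = FALSE))) else NULL,
    selection = do.call(rbind, c(selection, list(make.row.names = FALSE))),
    params = list(
      first_order = do.call(rbind, c(first_rows, list(make.row.names = FALSE))),
      second_order = do.call(rbind, c(second_rows, list(make.row.names = FALSE)))
    ),
    failures = if (length(failures))
      do.call(rbind, c(failures, list(make.row.names = FALSE))) else NULL,
    provenance = list(
      seed = seed, delta = delta, models = names(catalog), traits = traits,
      package_version = as.character(utils::packageVersion("segmix"))
    )
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' Write / read a report bundle
#'
#' CSV tables rounded to 2 decimals (the table convention for percentages
#' and effects) plus a machine-readable JSON sidecar at full precision; the
#' sidecar round-trips the bundle exactly.
#'
#' @param bundle a `"report_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write_report_bundle`); the restored bundle
#'   (`read_report_bundle`).
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round_df <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = 2L)
    df
  }
  tables <- list(descriptive = bundle$descriptive, aic = bundle$aic,
                 fitness = bundle$fitness, selection = bundle$selection,
                 first_order = bundle$params$first_order,
                 second_order = bundle$params$second_order,
                 failures = bundle$failures)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      utils::write.csv(round_df(as.data.frame(tables[[nm]])),
                       file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass(bundle), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", na = "null")
  invisible(dir)
}

#' @rdname write_report_bundle
#' @export
read_report_bundle <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop("no report.json in ", dir, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bundle <- list(
    descriptive = as.data.frame(raw$descriptive),
    aic = as.data.frame(raw$aic),
    fitness = if (!is.null(raw$fitness)) as.data.frame(raw$fitness),
    selection = as.data.frame(raw$selection),
    params = list(first_order = as.data.frame(raw$params$first_order),
                  second_order = as.data.frame(raw$params$second_order)),
    failures = if (!is.null(raw$failures)) as.data.frame(raw$failures),
    provenance = raw$provenance
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  strata: %d; models fitted: %s\n",
              nrow(x$selection), paste(x$provenance$models, collapse = ", ")))
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}
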