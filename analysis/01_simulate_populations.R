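#!/usr/bin/env Rscript
# Generate the four-generation study populations. The raw field phenotypes
# of the TMF2 (T01 x Mo17) and TXF2 (T01 x Xin3) crosses were never
# deposited, so each (population, trait, environment) is simulated from its
# published best-model parameterization: effects from the first-order
# tables, variances from the second-order tables, baseline anchored on the
# reported T01 mean, 200 F2 plants for E1 rows and 400 for E2 rows.
suppressMessages(library(segmix))

out_dir <- "results/populations"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

bank <- scenario_bank(n_parents = 10L, seed = 20260L)
study <- bank[!(names(bank) %in% c("null", "one_gene", "variance_dominated"))]

truth <- list()
for (nm in names(study)) {
  sc <- study[[nm]]
  tab <- simulate_population(sc)
  write_phenotypes(tab, file.path(out_dir, paste0(nm, ".csv")))
  gm <- genotype_means(sc$model, sc$effects)
  truth[[nm]] <- list(
    model = sc$model$code,
    effects = as.list(unclass(sc$effects)[sc$effects != 0]),
    sigma2_e = sc$sigma2_e, sigma2_pg = sc$sigma2_pg,
    n = as.list(sc$n), seed = sc$seed,
    f2_component_means = gm$F2$mean, f2_weights = gm$F2$weight)
  f2 <- generation_values(tab)$F2
  cat(sprintf("%-15s %-11s F2 n=%3d mean %8.2f sd %8.2f range [%.1f, %.1f]\n",
              nm, sc$model$code, length(f2), mean(f2), sd(f2),
              min(f2), max(f2)))
}
jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("\n%d populations written to %s (generating parameters in truth.json)\n",
            length(study), out_dir))
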