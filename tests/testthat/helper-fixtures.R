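# shared fixtures: everything is generated in code at test time

fast_opts <- function(seed = 1, restarts = 4L, tol = 1e-7, ...) {
  em_options(restarts = restarts, tol = tol, seed = seed, ...)
}

# small but well-separated single-gene dataset, quick to fit
demo_population <- function(seed = 11, n_f2 = 200L) {
  sc <- scenario("demo", "1MG-AD", genetic_effects(m = 0, da = 10, ha = 5),
                 sigma2_e = 4,
                 n = c(P1 = 10, P2 = 10, F1 = 10, F2 = n_f2), seed = seed)
  simulate_population(sc)
}

# a generic effect vector with no accidental ties between component means
generic_effects <- function(model, seed = 42) {
  set.seed(seed)
  theta <- stats::setNames(round(stats::runif(length(model$free_params),
                                              0.5, 3), 3),
                           model$free_params)
  eff <- drop(model$constraint %*% theta)
  class(eff) <- "genetic_effects"
  eff
}

expect_phenotypes_equal <- function(a, b) {
  expect_equal(as.character(a$generation), as.character(b$generation))
  for (col in c("population", "environment", "individual", "trait")) {
    expect_equal(a[[col]], b[[col]])
  }
  expect_equal(a$value, b$value, tolerance = 1e-12)
}
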