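test_that("EM recovers single-gene effects within Monte-Carlo error", {
  # MC SEs frozen from a 200-replicate simulation of this very scenario
  # (n = 10/10/10/400): sd(m) = 0.151, sd(da) = 0.158, sd(ha) = 0.200
  sc <- scenario("mc", "1MG-AD", genetic_effects(m = 0, da = 10, ha = 5),
                 sigma2_e = 4, n = c(P1 = 10, P2 = 10, F1 = 10, F2 = 400))
  dat <- simulate_population(sc, seed = 5001)
  fit <- em_fit(dat, "1MG-AD", fast_opts(seed = 1, restarts = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$effects[["da"]] - 10), 3 * 0.158)
  expect_lt(abs(fit$effects[["ha"]] - 5), 3 * 0.200)
  expect_lt(abs(fit$effects[["m"]]), 3 * 0.151)
})

test_that("the lnL trace is non-decreasing for every model family", {
  dat <- demo_population(seed = 21)
  for (code in c("1MG-AD", "2MG-EA", "2MG-ADI", "MX1-AD-AD", "MX2-ADI-AD",
                 "PG-AD", "0MG")) {
    fit <- em_fit(dat, code, fast_opts(seed = 2, restarts = 3))
    expect_true(all(diff(fit$trace) > -1e-6),
                label = sprintf("monotone trace for %s", code))
    expect_equal(fit$aic, 2 * fit$k - 2 * fit$lnL)
    expect_equal(unname(rowSums(fit$posteriors)),
                 rep(1, nrow(fit$posteriors)), tolerance = 1e-12)
  }
})

test_that("the null model collapses to the pooled single-normal fit", {
  set.seed(33)
  noise <- list(P1 = rnorm(10, 50, 5), P2 = rnorm(10, 50, 5),
                F1 = rnorm(10, 50, 5), F2 = rnorm(100, 50, 5))
  fit <- em_fit(noise, "0MG", fast_opts(seed = 3, restarts = 2))
  y <- unlist(noise)
  v_mle <- mean((y - mean(y))^2)
  lnL_single <- sum(stats::dnorm(y, mean(y), sqrt(v_mle), log = TRUE))
  expect_equal(fit$lnL, lnL_single, tolerance = 1e-6)
})

test_that("initializing at the truth never yields a worse likelihood", {
  sc <- scenario_bank()$TMF2_VSG_E1
  dat <- simulate_population(sc, seed = 91)
  opts <- fast_opts(seed = 4, restarts = 3)
  fit_default <- em_fit(dat, sc$model, opts)
  fit_truth <- em_fit(dat, sc$model, opts,
                      init = list(theta = sc$effects, sigma2_e = sc$sigma2_e,
                                  sigma2_pg = sc$sigma2_pg))
  expect_gte(fit_truth$lnL, fit_default$lnL - 1e-6)
})

test_that("nested models are ordered in maximized likelihood", {
  dat <- demo_population(seed = 55)
  opts <- fast_opts(seed = 5, restarts = 4)
  lnls <- vapply(c("2MG-A", "2MG-AD", "MX2-ADI-AD"),
                 function(code) em_fit(dat, code, opts)$lnL, 0)
  expect_gte(lnls[["2MG-AD"]], lnls[["2MG-A"]] - 1e-6)
  expect_gte(lnls[["MX2-ADI-AD"]], lnls[["2MG-AD"]] - 1e-6)
})

test_that("structural constraints hold exactly in fitted effects", {
  dat <- demo_population(seed = 77)
  fit_ea <- em_fit(dat, "2MG-EA", fast_opts(seed = 6, restarts = 2))
  expect_identical(fit_ea$effects[["da"]], fit_ea$effects[["db"]])
  fit_cd <- em_fit(dat, "2MG-CD", fast_opts(seed = 6, restarts = 2))
  expect_identical(fit_cd$effects[["ha"]], fit_cd$effects[["da"]])
  expect_identical(fit_cd$effects[["hb"]], fit_cd$effects[["db"]])
  fit_a <- em_fit(dat, "2MG-A", fast_opts(seed = 6, restarts = 2))
  expect_identical(unname(unclass(fit_a$effects)[c("ha", "hb", "i", "jab",
                                                   "jba", "l")]),
                   rep(0, 6))
})

test_that("the two major loci are reported in canonical |da| >= |db| order", {
  sc <- scenario("canon", "2MG-A",
                 genetic_effects(m = 0, da = 2, db = 9),
                 sigma2_e = 1, n = c(P1 = 10, P2 = 10, F1 = 10, F2 = 300),
                 seed = 13)
  fit <- em_fit(simulate_population(sc), "2MG-A", fast_opts(seed = 7))
  expect_gte(abs(fit$effects[["da"]]), abs(fit$effects[["db"]]))
  # the generating mixture used (2, 9); canonical reporting is (9, 2)
  expect_equal(unname(unclass(fit$effects)[c("da", "db")]), c(9, 2),
               tolerance = 0.15)
})

test_that("preconditions are enforced", {
  dat <- demo_population(seed = 99, n_f2 = 40L)
  vals <- generation_values(dat)
  expect_error(em_fit(vals[c("P1", "P2", "F2")], "1MG-AD"), "missing: F1")
  expect_error(em_fit(vals, "1MG-AD", em_options(min_f2 = 100L)),
               "below minimum")
  const <- list(P1 = rep(1, 5), P2 = rep(1, 5), F1 = rep(1, 5),
                F2 = rep(1, 50))
  expect_error(em_fit(const, "1MG-AD", fast_opts()), "degenerate")
})

test_that("fits are deterministic under a fixed option seed", {
  dat <- demo_population(seed = 101)
  f1 <- em_fit(dat, "MX2-A-AD", fast_opts(seed = 8))
  f2 <- em_fit(dat, "MX2-A-AD", fast_opts(seed = 8))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$lnL, f2$lnL)
})
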