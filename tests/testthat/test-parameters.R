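mock_fit <- function(model, effects, sigma2_e = 1, sigma2_pg = 0) {
  spec <- segmix:::mixture_spec(model, effects, sigma2_e, sigma2_pg)
  structure(list(model = model$code, effects = effects,
                 sigma2_e = sigma2_e, sigma2_pg = sigma2_pg,
                 converged = TRUE, spec = spec),
            class = "seg_fit")
}

test_that("first_order recovers effects exactly from noiseless means", {
  for (code in c("1MG-AD", "2MG-A", "2MG-EA", "2MG-CD", "MX2-A-AD",
                 "MX2-ADI-AD")) {
    model <- model_catalog(code)[[code]]
    eff <- generic_effects(model, seed = 19)
    fit <- mock_fit(model, eff)
    expect_equal(unclass(first_order(fit)), unclass(eff), tolerance = 1e-10)
  }
})

test_that("first_order reproduces the EM effects on a real fit", {
  dat <- demo_population(seed = 41)
  fit <- em_fit(dat, "1MG-AD", fast_opts(seed = 12, restarts = 2))
  expect_equal(unclass(first_order(fit)), unclass(fit$effects),
               tolerance = 1e-9)
})

test_that("rank-deficient designs error naming confounded effects", {
  model <- model_catalog("MX2-ADI-ADI")[["MX2-ADI-ADI"]]
  eff <- genetic_effects(m = 1, da = 2, db = 1, ha = 0.5, hb = 0.2,
                         i = 0.1, jab = 0.3, jba = 0.2, l = 0.4,
                         d_poly = 0.5, h_poly = 0.6, i_poly = 0.1,
                         l_poly = 0.2)
  fit <- mock_fit(model, eff, sigma2_e = 1, sigma2_pg = 0.5)
  expect_error(first_order(fit), "confounded")
})

test_that("negating phenotypes negates the odd genetic effects", {
  sc <- scenario("sgn", "2MG-A", genetic_effects(m = 2, da = 8, db = 4),
                 sigma2_e = 1, n = c(P1 = 10, P2 = 10, F1 = 10, F2 = 300),
                 seed = 17)
  dat <- generation_values(simulate_population(sc))
  neg <- lapply(dat, function(v) -v)
  f_pos <- em_fit(dat, "2MG-A", fast_opts(seed = 13))
  f_neg <- em_fit(neg, "2MG-A", fast_opts(seed = 13))
  for (nm in c("m", "da", "db")) {
    expect_equal(f_neg$effects[[nm]], -f_pos$effects[[nm]], tolerance = 1e-3)
  }
})

test_that("variance components reproduce the published heritability arithmetic", {
  # reported GYP of the T01 x Xin3 cross: sigma2_mg 560.88, F2 SD 24.15
  model <- model_catalog("2MG-A")[["2MG-A"]]
  sigma2_p <- 24.15^2
  fit <- mock_fit(model, genetic_effects(m = 50, da = 26.56, db = -6.84),
                  sigma2_e = sigma2_p - 560.88)
  d <- 24.15 / sqrt(2)  # two points with exactly the reported F2 variance
  vc <- second_order(fit, list(F2 = c(50 - d, 50 + d)))
  expect_equal(vc$sigma2_p, sigma2_p, tolerance = 1e-10)
  expect_equal(vc$sigma2_mg, 560.88, tolerance = 1e-8)
  expect_equal(vc$h2_mg, 96.17, tolerance = 0.02)

  # reported VSG of the T01 x Mo17 cross: sigma2_pg 10.32, F2 SD 25.66
  model2 <- model_catalog("MX2-A-AD")[["MX2-A-AD"]]
  sigma2_p2 <- 25.66^2
  fit2 <- mock_fit(model2,
                   genetic_effects(m = 30, da = 28.28, db = 17.95,
                                   d_poly = -18.34, h_poly = 42.74),
                   sigma2_e = sigma2_p2 - 631.67 - 10.32, sigma2_pg = 10.32)
  d2 <- 25.66 / sqrt(2)
  vc2 <- second_order(fit2, list(F2 = c(50 - d2, 50 + d2)))
  expect_equal(vc2$h2_pg, 1.57, tolerance = 0.02)
  expect_equal(vc2$h2_mg, 95.95, tolerance = 0.02)
})

test_that("the decomposition closes exactly when nothing is floored", {
  dat <- demo_population(seed = 43)
  fit <- em_fit(dat, "1MG-AD", fast_opts(seed = 14, restarts = 2))
  vc <- second_order(fit, dat)
  if (!vc$floored) {
    expect_equal(vc$sigma2_mg + vc$sigma2_pg + vc$sigma2_e, vc$sigma2_p,
                 tolerance = 1e-10)
  }
  expect_gte(vc$h2_mg, 0)
  expect_gte(vc$h2_pg, 0)
  expect_lte(vc$h2_mg + vc$h2_pg, 100 + 1e-10)
})

test_that("pure-noise fits attribute no variance to major genes", {
  set.seed(23)
  noise <- list(P1 = rnorm(10, 50, 5), P2 = rnorm(10, 50, 5),
                F1 = rnorm(10, 50, 5), F2 = rnorm(200, 50, 5))
  fit <- em_fit(noise, "0MG", fast_opts(seed = 15, restarts = 2))
  vc <- suppressWarnings(second_order(fit, noise))
  expect_lt(vc$h2_mg, 10)
  expect_identical(vc$h2_pg, 0)
})

test_that("heritability validates its inputs", {
  expect_equal(heritability(50, 100), 50)
  expect_error(heritability(-1, 100))
  expect_error(heritability(1, 0))
})
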