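test_that("PIT values follow the fitted CDF", {
  g <- list(means = 5, weights = 1, var = 4)
  expect_equal(pit(5, g), 0.5)
  expect_lt(pit(-1e6, g), 1e-12)
  expect_gt(pit(1e6, g), 1 - 1e-12)
  spec <- segmix:::mixture_spec(model_catalog("1MG-A")[["1MG-A"]],
                                genetic_effects(m = 0, da = 3), 1)
  expect_equal(pit(0, spec, "F2"), 0.5)  # symmetric mixture around 0
  expect_error(pit(0, spec), "generation")
})

test_that("the mixture CDF agrees with a Monte-Carlo empirical CDF", {
  means <- c(-3, 0, 4); weights <- c(0.25, 0.5, 0.25); var <- 1.5
  set.seed(42)
  n <- 1e6
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  draws <- rnorm(n, means[comp], sqrt(var))
  grid <- seq(-7, 8, length.out = 200)
  emp <- ecdf(draws)(grid)
  theo <- segmix:::mixture_cdf(grid, means, weights, var)
  expect_lt(max(abs(emp - theo)), 0.002)
})

test_that("uniformity statistics reproduce closed forms", {
  n <- 20
  grid <- (2 * seq_len(n) - 1) / (2 * n)
  u <- uniformity_stats(grid)
  expect_equal(u[["U1sq"]], 0, tolerance = 1e-24)

  # all transforms at 1: pi_k(1) = sqrt(3), sqrt(5), sqrt(7)
  u1 <- uniformity_stats(rep(1, 4))
  expect_equal(unname(u1), c(4 * 3, 4 * 5, 4 * 7))
})

test_that("Cramer-von Mises statistic reproduces closed forms", {
  n <- 16
  grid <- (2 * seq_len(n) - 1) / (2 * n)
  expect_equal(cvm_stat(grid), 1 / (12 * n))
  expect_equal(cvm_stat(0.5), 1 / 12)
})

test_that("Kolmogorov statistic matches exhaustive enumeration at n = 3", {
  grid4 <- (2 * (1:4) - 1) / (2 * 4)
  expect_equal(ks_stat(grid4), 1 / 8)
  expect_equal(ks_stat(1), 1)
  set.seed(9)
  for (r in 1:20) {
    e <- sort(runif(3))
    brute <- max(vapply(1:3, function(i) {
      max(i / 3 - e[i], e[i] - (i - 1) / 3)
    }, 0))
    expect_equal(ks_stat(sample(e)), brute)
  }
})

test_that("all five statistics ignore input order", {
  set.seed(10)
  e <- runif(50)
  shuf <- sample(e)
  expect_equal(uniformity_stats(e), uniformity_stats(shuf))
  expect_equal(cvm_stat(e), cvm_stat(shuf))
  expect_equal(ks_stat(e), ks_stat(shuf))
})

test_that("gof_report flags exactly the statistics over their thresholds", {
  dat <- demo_population(seed = 31)
  fit <- em_fit(dat, "1MG-AD", fast_opts(seed = 11, restarts = 2))
  rep_tab <- gof_report(fit, dat)
  expect_setequal(rep_tab$generation, c("P1", "P2", "F1", "F2"))
  expect_true(all(rep_tab[c("U1sq", "U2sq", "U3sq", "nWsq", "Dn")] >= 0))
  expect_true(all(rep_tab$Dn <= 1))
  expect_identical(rep_tab$U1sq_sig, rep_tab$U1sq > 3.841)
  expect_identical(rep_tab$U3sq_sig, rep_tab$U3sq > 3.841)
  expect_identical(rep_tab$nWsq_sig, rep_tab$nWsq > 0.461)
  sig_cols <- paste0(c("U1sq", "U2sq", "U3sq", "nWsq", "Dn"), "_sig")
  expect_equal(rep_tab$n_significant, unname(rowSums(rep_tab[sig_cols])))
})

test_that("select_best applies the two-stage rule with AIC tie-breaks", {
  mk_fit <- function(code, aic) {
    structure(list(model = code, aic = aic), class = "seg_fit")
  }
  mk_rep <- function(nsig) data.frame(n_significant = nsig)
  one <- select_best(list(mk_fit("2MG-EA", 100)), list("2MG-EA" = mk_rep(0)))
  expect_equal(one$best, "2MG-EA")

  # equal significant counts: the lower AIC wins
  fits <- list(mk_fit("A1", 100), mk_fit("A2", 101))
  names(fits) <- c("A1", "A2")
  reps <- list(A1 = mk_rep(1), A2 = mk_rep(1))
  expect_equal(select_best(fits, reps)$best, "A1")

  # fewer significant statistics beats lower AIC inside the band
  reps2 <- list(A1 = mk_rep(3), A2 = mk_rep(0))
  expect_equal(select_best(fits, reps2)$best, "A2")

  # outside the band the cleaner model is not a candidate
  fits3 <- list(mk_fit("A1", 100), mk_fit("A2", 110))
  names(fits3) <- c("A1", "A2")
  sel3 <- select_best(fits3, list(A1 = mk_rep(3), A2 = mk_rep(0)))
  expect_equal(sel3$best, "A1")
  expect_equal(sel3$candidates, "A1")

  expect_error(select_best(list()), "no successful fits")
})
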