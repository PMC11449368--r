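test_that("noiseless logistic data are recovered with near-zero RSS", {
  t <- seq(0, 40, by = 5)
  series <- data.frame(t = t, area = 3000 / (1 + exp(5 - 0.25 * t)))
  fit <- fit_logistic(series)
  expect_true(fit$converged)
  expect_equal(fit$a, 3000, tolerance = 1e-4)
  expect_equal(fit$b, 5, tolerance = 1e-4)
  expect_equal(fit$c, -0.25, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-6)
})

test_that("constant series are flagged non-identifiable with c = 0", {
  series <- data.frame(t = c(0, 10, 20, 30), area = rep(500, 4))
  fit <- fit_logistic(series)
  expect_false(fit$identifiable)
  expect_identical(fit$c, 0)
  expect_equal(compute_glad(fit, 40), 500, ignore_attr = TRUE)
  expect_true(attr(compute_glad(fit, 40), "constant_limit"))
})

test_that("input contracts are enforced", {
  expect_error(fit_logistic(data.frame(t = c(0, 5, 10), area = c(1, 2, 3))),
               "4 distinct")
  expect_error(fit_logistic(data.frame(t = c(0, 10, 5, 20),
                                       area = c(1, 2, 3, 4))),
               "strictly increasing")
  fit <- list(a = 100, b = 1, c = -0.2, converged = TRUE)
  expect_error(compute_glad(fit, 0), "positive")
  expect_error(compute_glad(list(a = 1, b = 0, c = 0, converged = FALSE)),
               "converge")
})

test_that("noisy series recover the truth within Monte-Carlo tolerance", {
  series <- simulate_leaf_area_series(3000, 5, -0.25, noise_sd = 50,
                                      times = seq(0, 40, 2.5),
                                      n_individuals = 20, seed = 8,
                                      jitter_frac = 0)
  tab <- glad_table(series)
  expect_true(all(tab$converged))
  # a is estimated per individual from 17 noisy points; check the panel mean
  expect_equal(mean(tab$a), 3000, tolerance = 0.02)
  expect_equal(mean(tab$c), -0.25, tolerance = 0.05)
})

test_that("closed-form GLAD equals adaptive quadrature on random draws", {
  set.seed(12)
  for (r in 1:100) {
    a <- runif(1, 500, 5000)
    b <- runif(1, -2, 8)
    c <- runif(1, -0.6, 0.4)
    w <- runif(1, 10, 60)
    fit <- list(a = a, b = b, c = c, converged = TRUE)
    closed <- as.numeric(compute_glad(fit, w))
    quad <- stats::integrate(function(t) a / (1 + exp(b + c * t)), 0, w,
                             rel.tol = 1e-10)$value / w
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("GLAD is bounded by and monotone in the asymptote", {
  set.seed(13)
  for (r in 1:25) {
    a <- runif(1, 100, 4000)
    b <- runif(1, -3, 6)
    c <- runif(1, -0.5, 0.5)
    g <- as.numeric(compute_glad(list(a = a, b = b, c = c, converged = TRUE)))
    g2 <- as.numeric(compute_glad(list(a = 2 * a, b = b, c = c,
                                       converged = TRUE)))
    expect_lte(g, a)
    expect_equal(g2, 2 * g, tolerance = 1e-12)  # linear, hence monotone in a
  }
  # saturated curve: b -> -Inf pushes the daily mean to the asymptote
  sat <- compute_glad(list(a = 1234, b = -50, c = -0.1, converged = TRUE), 40)
  expect_equal(as.numeric(sat), 1234, tolerance = 1e-6)
})

test_that("VSG is the percent area ratio with strict domain checks", {
  expect_equal(compute_vsg(50, 100), 50)
  expect_equal(compute_vsg(0, 100), 0)
  expect_equal(compute_vsg(100, 100), 100)
  expect_error(compute_vsg(10, 0), "area_flowering")
  expect_error(compute_vsg(-1, 10), "area_maturity")
  expect_warning(compute_vsg(150, 100), "above 100")
})

test_that("leaf-area simulation is deterministic and round-trips", {
  s1 <- simulate_leaf_area_series(3000, 5, -0.25, noise_sd = 25,
                                  n_individuals = 5, seed = 77)
  s2 <- simulate_leaf_area_series(3000, 5, -0.25, noise_sd = 25,
                                  n_individuals = 5, seed = 77)
  expect_identical(s1, s2)

  noiseless <- simulate_leaf_area_series(3000, 5, -0.25, noise_sd = 0,
                                         n_individuals = 3, seed = 78)
  truth <- attr(noiseless, "truth")
  tab <- glad_table(noiseless)
  expect_equal(tab$a, truth$a, tolerance = 1e-3)
  expect_equal(tab$c, truth$c, tolerance = 1e-3)
})
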