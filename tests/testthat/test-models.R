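PUBLISHED_CODES <- c("1MG-AD", "1MG-EAD", "2MG-A", "2MG-EA", "2MG-CD",
                     "2MG-EAD", "MX2-ADI-ADI", "MX2-ADI-AD", "MX2-AD-AD",
                     "MX2-A-AD")

test_that("the catalog has 24 unique models including all published codes", {
  cat24 <- model_catalog()
  expect_length(cat24, 24L)
  codes <- vapply(cat24, `[[`, "", "code")
  expect_equal(anyDuplicated(codes), 0L)
  expect_true(all(PUBLISHED_CODES %in% codes))
})

test_that("subset selection validates codes", {
  one <- model_catalog("2MG-EA")[["2MG-EA"]]
  expect_equal(one$free_params, c("m", "da"))
  expect_equal(one$constraint["db", "da"], 1)  # equal additive constraint
  expect_error(model_catalog(character(0)), "empty")
  expect_error(model_catalog("3MG-XYZ"), "unknown model code")
})

test_that("parameter counts follow the k convention", {
  cat24 <- model_catalog(c("2MG-EA", "1MG-AD", "MX2-ADI-AD"))
  expect_equal(cat24[["2MG-EA"]]$k, 3L)
  expect_equal(cat24[["1MG-AD"]]$k, 4L)
  expect_equal(cat24[["MX2-ADI-AD"]]$k, 13L)
})

test_that("2MG-EA collapses to the binomial five-component mixture", {
  gm <- genotype_means("2MG-EA", genetic_effects(da = 1, db = 1))
  expect_equal(gm$F2$mean, c(2, 1, 0, -1, -2))
  expect_equal(gm$F2$weight, c(1, 4, 6, 4, 1) / 16)
  expect_equal(gm$P1, 2)
  expect_equal(gm$P2, -2)
  expect_equal(gm$F1, 0)
})

test_that("zero effects collapse every generation to the baseline", {
  for (code in c("2MG-A", "1MG-AD", "MX2-ADI-AD")) {
    gm <- genotype_means(code, genetic_effects(m = 7))
    expect_equal(gm$P1, 7)
    expect_equal(gm$P2, 7)
    expect_equal(gm$F1, 7)
    expect_equal(nrow(gm$F2), 1L)
    expect_identical(gm$F2$weight, 1)
    expect_equal(gm$F2$mean, 7)
  }
})

test_that("structural-zero violations are rejected, not ignored", {
  expect_error(genotype_means("2MG-A", genetic_effects(da = 1, ha = 2)),
               "structural")
  expect_error(genotype_means("2MG-EA", genetic_effects(da = 1, db = 2)),
               "structural")
})

test_that("the two-locus epistatic means match independent hand evaluation", {
  # reported VSG effects of the TXF2 cross, baseline anchored at 0
  da <- 29.65; db <- 4.62; ha <- -7.61; hb <- -4.95
  i <- 5.24; jab <- 13.73; jba <- 1.90; l <- 29.46
  d_poly <- -6.06; h_poly <- 20.30
  gm <- genotype_means("MX2-ADI-AD", genetic_effects(
    m = 0, da = da, db = db, ha = ha, hb = hb, i = i, jab = jab,
    jba = jba, l = l, d_poly = d_poly, h_poly = h_poly))
  # independent evaluation of the nine genotypic values + F2 polygene shift
  hand <- c(AABB = da + db + i,     AABb = da + hb + jab,
            AAbb = da - db - i,     AaBB = ha + db + jba,
            AaBb = ha + hb + l,     Aabb = ha - db - jba,
            aaBB = -da + db - i,    aaBb = -da + hb - jab,
            aabb = -da - db + i) + h_poly / 2
  expect_length(gm$F2$mean, 9L)
  expect_equal(sort(gm$F2$mean), sort(unname(hand)), tolerance = 1e-12)
  expect_equal(gm$P1, da + db + i + d_poly)
  expect_equal(gm$P2, -da - db + i - d_poly)
  expect_equal(gm$F1, ha + hb + l + h_poly)
})

test_that("F2 weights are exactly Mendelian and sum to one for all models", {
  for (model in model_catalog()) {
    gm <- genotype_means(model, generic_effects(model))
    expect_identical(sum(gm$F2$weight), 1)
    den <- if (model$n_major_genes == 2L) 16 else 4
    expect_true(all(gm$F2$weight * den == round(gm$F2$weight * den)))
  }
})

test_that("swapping gene labels permutes F2 means, preserving the mixture", {
  eff <- genetic_effects(m = 1, da = 3, db = 1.2, ha = 0.7, hb = -0.5,
                         i = 0.4, jab = 0.9, jba = -0.3, l = 0.6)
  sw <- genetic_effects(m = 1, da = 1.2, db = 3, ha = -0.5, hb = 0.7,
                        i = 0.4, jab = -0.3, jba = 0.9, l = 0.6)
  a <- genotype_means("2MG-ADI", eff)
  b <- genotype_means("2MG-ADI", sw)
  expect_equal(sort(a$F2$mean), sort(b$F2$mean))
  expect_equal(sum(a$F2$mean * a$F2$weight), sum(b$F2$mean * b$F2$weight))
})

test_that("design matrix is the exact linear form of the mean structure", {
  for (model in model_catalog()) {
    X <- design_matrix(model)
    eff <- generic_effects(model)
    theta <- unclass(eff)[model$free_params]
    gm <- genotype_means(model, eff)
    expect_equal(drop(X %*% theta),
                 c(P1 = gm$P1, P2 = gm$P2, F1 = gm$F1,
                   stats::setNames(gm$F2$mean,
                                   paste0("F2:", gm$F2$component))),
                 tolerance = 1e-14)
    expect_equal(drop(X %*% numeric(length(theta))),
                 stats::setNames(numeric(nrow(X)), rownames(X)))
  }
})

test_that("equal-additive and complete-dominance constraints are structural", {
  ea_model <- model_catalog("2MG-EA")[["2MG-EA"]]
  ea_eff <- drop(ea_model$constraint %*% c(m = 0, da = -2))
  expect_identical(abs(ea_eff[["da"]]), abs(ea_eff[["db"]]))
  cd_model <- model_catalog("2MG-CD")[["2MG-CD"]]
  eff <- drop(cd_model$constraint %*% c(m = 0, da = 3, db = 1))
  expect_identical(eff[["ha"]], eff[["da"]])
  expect_identical(eff[["hb"]], eff[["db"]])
  eads <- model_catalog("2MG-EAD")[["2MG-EAD"]]
  eff2 <- drop(eads$constraint %*% c(m = 0, da = 2))
  expect_identical(unname(eff2[c("db", "ha", "hb")]), rep(2, 3))
})

test_that("catalog JSON export is self-consistent", {
  json <- catalog_json()
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_length(parsed, 24L)
  w <- vapply(parsed, function(mj) sum(unlist(mj$f2_weights)), 0)
  expect_true(all(abs(w - 1) < 1e-15))
})
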