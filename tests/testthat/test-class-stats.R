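test_that("the class-age GLM is null-calibrated and recovers planted rate ratios", {
  set.seed(61)
  tab0 <- data.frame(class_label = rep(c("reproductive", "worker"),
                                       each = 20000),
                     stratum = rpois(40000, 4) + 1)
  g0 <- glmMeanStratum(tab0)
  expect_lt(abs(unname(g0$z)), 2.5)

  tab1 <- data.frame(class_label = rep(c("reproductive", "worker"),
                                       each = 20000),
                     stratum = c(rpois(20000, 4), rpois(20000, 6)))
  g1 <- glmMeanStratum(tab1, ref = "reproductive")
  expect_lt(abs(unname(g1$coefficient) - log(1.5)),
            3 * unname(g1$std_error))
  expect_equal(g1$df, 40000 - 2)
  expect_gt(unname(g1$z), 0)
})

test_that("overdispersion triggers the quasi-Poisson switch; underdispersion inflates z", {
  set.seed(62)
  over <- data.frame(class_label = rep(c("a", "b"), each = 5000),
                     stratum = rnbinom(10000, mu = 5, size = 1.2) + 1)
  go <- glmMeanStratum(over)
  expect_gt(go$dispersion, 1.2)
  expect_identical(go$family_used, "quasipoisson")
  expect_lt(abs(unname(go$z)), abs(unname(go$z_poisson)))

  # an underdispersed integer response: scaled SEs smaller, |z| larger
  under <- data.frame(class_label = rep(c("a", "b"), each = 3000),
                      stratum = rep(c(3L, 4L), 3000))
  gu <- glmMeanStratum(under)
  expect_lt(gu$dispersion, 1)
  expect_identical(gu$family_used, "poisson")
  expect_gt(abs(unname(gu$z_quasi)), abs(unname(gu$z_poisson)))

  expect_error(glmMeanStratum(data.frame(class_label = c("a", "a", "b", "b"),
                                         stratum = c(3, 3, 3, 3))),
               "variance")
})

test_that("condensed and raw strata give the same coefficient sign under a monotone age shift", {
  lin <- defaultLineage()
  set.seed(63)
  raw <- data.frame(
    class_label = rep(c("reproductive", "worker"), each = 4000),
    stratum = pmin(pmax(c(rpois(4000, 4), rpois(4000, 7)), 1), 19))
  cond <- raw
  cond$stratum <- match(condense(raw$stratum, lin), condensedCategories(lin))
  z_raw <- unname(glmMeanStratum(raw, ref = "reproductive")$z)
  z_cond <- unname(glmMeanStratum(cond, ref = "reproductive")$z)
  expect_identical(sign(z_raw), sign(z_cond))
})

test_that("contingency residuals reproduce the textbook formulas", {
  # perfect independence: X2 = 0, everything flagged none
  indep <- outer(c(20, 40), c(10, 30, 60)) / 100
  ri <- contingencyResiduals(indep)
  expect_equal(ri$chi_square, 0)
  expect_true(all(ri$cells$std_pearson_residual == 0))
  expect_true(all(ri$cells$significance == "none"))

  # forced arithmetic on the 2x2 [[30,10],[10,30]]
  r2 <- contingencyResiduals(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(r2$chi_square, 20)
  expect_equal(r2$df, 1)
  c11 <- r2$cells[r2$cells$row == "row1" & r2$cells$col == "col1", ]
  expect_equal(c11$std_pearson_residual, 10 / sqrt(5), tolerance = 1e-12)
  expect_identical(c11$significance, "p<0.001")
  expect_identical(c11$direction, "over")

  # random tables against the oracle, margins and permutations
  set.seed(64)
  for (k in 1:20) {
    O <- matrix(rpois(18, 30) + 1, 3, 6)
    got <- contingencyResiduals(O)
    want <- oracleChisq(O)
    expect_equal(got$chi_square, want$X2, tolerance = 1e-10)
    expect_equal(matrix(got$cells$std_pearson_residual, 3, 6),
                 unname(want$stdres), tolerance = 1e-10)
    resid_o_e <- matrix(got$cells$observed - got$cells$expected, 3, 6)
    expect_equal(rowSums(resid_o_e), rep(0, 3), tolerance = 1e-9)
    expect_equal(colSums(resid_o_e), rep(0, 6), tolerance = 1e-9)
    perm <- contingencyResiduals(O[sample(3), sample(6)])
    expect_equal(perm$chi_square, got$chi_square, tolerance = 1e-10)
  }

  expect_error(contingencyResiduals(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("GO over-representation equals the hypergeometric tail", {
  bg <- paste0("g", 1:20)
  # the 5-of-5 case: p = 1 / C(20, 5)
  ann <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1",
                    term_name = "five")
  res <- goEnrichment(paste0("g", 1:5), bg, ann)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$enriched)

  # a term absent from the set is never flagged
  ann2 <- data.frame(gene_id = paste0("g", 6:17), term_id = "T2")
  res2 <- goEnrichment(paste0("g", 1:5), bg, ann2)
  expect_gte(res2$p, 0.5)
  expect_false(res2$enriched)

  # random annotation tables against brute-force summation
  set.seed(65)
  for (k in 1:15) {
    N <- 40; n <- 12
    bgk <- paste0("g", 1:N)
    set <- sample(bgk, n)
    annk <- data.frame(gene_id = sample(bgk, 18), term_id = "T")
    got <- goEnrichment(set, bgk, annk)
    kk <- length(intersect(annk$gene_id, set))
    expect_equal(got$p, oracleHyperP(kk, 18, n, N), tolerance = 1e-12)
    expect_gte(got$p, 0)
    expect_lte(got$p, 1)
  }

  # monotone decreasing in k at fixed margins
  ps <- sapply(0:5, function(k) {
    ann_k <- data.frame(gene_id = c(paste0("g", seq_len(k)),
                                    paste0("g", 10 + seq_len(5 - k))),
                        term_id = "T")
    goEnrichment(paste0("g", 1:5), bg, ann_k)$p
  })
  expect_true(all(diff(ps) < 0))

  expect_error(goEnrichment(c("g1", "zz"), bg, ann), "zz")
})
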