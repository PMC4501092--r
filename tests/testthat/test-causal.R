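test_that("partial correlation reduces to Pearson with no covariates", {
  set.seed(61)
  y <- rnorm(50); x <- rnorm(50)
  pc <- partial_correlation(y, x)
  expect_equal(pc$r, cor(y, x), tolerance = 1e-14)
  expect_equal(pc$k, 0L)
})

test_that("partial correlation matches closed-form and inverse-matrix oracles", {
  set.seed(62)
  for (i in 1:20) {
    n <- 60
    z <- rnorm(n)
    x <- 0.7 * z + rnorm(n)
    y <- -0.4 * z + 0.3 * x + rnorm(n)
    pc <- partial_correlation(y, x, cbind(z))
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$r, closed, tolerance = 1e-10)
  }
  # multi-covariate: inverse of the joint correlation matrix
  set.seed(63)
  for (i in 1:10) {
    n <- 80
    Z <- matrix(rnorm(n * 4), n)
    x <- Z %*% runif(4, -1, 1) + rnorm(n)
    y <- Z %*% runif(4, -1, 1) + 0.5 * x + rnorm(n)
    pc <- partial_correlation(y, x, Z)
    expect_equal(pc$r, oracle_pcor_inverse(as.vector(y), as.vector(x), Z),
                 tolerance = 1e-8)
  }
})

test_that("conditioning on the mediator silences a chain association", {
  set.seed(64)
  n <- 10000
  x <- rnorm(n)
  m <- x + rnorm(n)
  y <- m + rnorm(n)          # y depends on x only through m
  expect_gt(partial_correlation(y, x)$r, 0.4)
  expect_lt(abs(partial_correlation(y, x, cbind(m))$r), 0.03)
})

test_that("a pure-noise covariate barely changes the partial correlation", {
  set.seed(65)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  r0 <- partial_correlation(y, x)$r
  r1 <- partial_correlation(y, x, cbind(rnorm(n)))$r
  expect_lt(abs(r1 - r0), 0.05)
})

test_that("collinear covariates are dropped to an independent subset", {
  set.seed(66)
  n <- 40
  z <- rnorm(n)
  C <- cbind(z, 2 * z, rnorm(n))      # rank 2
  pc <- partial_correlation(rnorm(n), rnorm(n), C)
  expect_equal(pc$k, 2L)
  expect_equal(pc$dropped, 1L)
  # constant covariate dropped too
  pc2 <- partial_correlation(rnorm(n), rnorm(n), cbind(rep(1, n), z))
  expect_equal(pc2$k, 1L)
  expect_error(partial_correlation(rnorm(5), rnorm(5), matrix(rnorm(20), 5)),
               "covariates")
})

test_that("single-gene test separates direct drivers from promoter-confounded genes", {
  ds <- small_sim()
  clusters <- cluster_probes(ds$annotation)
  surv_direct <- surv_conf <- marg_conf <- 0L
  for (co in ds$cohorts) {
    expr <- preprocess_expression(co$expr)
    meth <- filter_and_impute(co$meth)
    rb <- summarize_regions(meth, clusters)
    idx <- instability_indices(meth, clusters, co$sheet)
    canc <- co$sheet$sample_id[co$sheet$status == "cancer"]
    idx <- idx[idx$sample_id %in% canc, ]
    pm <- promoter_methylation(rb, clusters, c("UHRF1", "EYA4"))
    ru <- single_gene_causal_test("UHRF1", expr, pm["UHRF1", ], idx)
    ra <- single_gene_causal_test("EYA4", expr, pm["EYA4", ], idx)
    surv_direct <- surv_direct + ru$survives[ru$index == "HyperZ"]
    surv_conf <- surv_conf + ra$survives[ra$index == "HyperZ"]
    mr <- ra$marginal_r[ra$index == "HyperZ"]
    marg_conf <- marg_conf + (2 * pnorm(-abs(fisher_z(mr)) *
                                          sqrt(length(canc) - 3)) < 0.05)
  }
  n_c <- length(ds$cohorts)
  expect_equal(surv_direct, n_c)           # model C survives everywhere
  expect_equal(marg_conf, n_c)             # model A is marginally associated
  expect_lt(surv_conf, n_c / 2)            # ... but its promoter explains it

  # gene without a promoter cluster is flagged untestable
  co <- ds$cohorts[[1]]
  expr <- preprocess_expression(co$expr)
  meth <- filter_and_impute(co$meth)
  idx <- instability_indices(meth, clusters, co$sheet)
  r0 <- single_gene_causal_test("BG001", expr, NULL, idx)
  expect_false(any(r0$testable))
})

test_that("full model silences the driver-correlated passenger but not the drivers", {
  ds <- small_sim()
  clusters <- cluster_probes(ds$annotation)
  genes <- c("UHRF1", "WHSC1", "CBX7", "EYA4", "EZH2")
  surv <- matrix(0L, length(genes), 2, dimnames = list(genes, c("HyperZ", "HypoZ")))
  for (co in ds$cohorts) {
    expr <- preprocess_expression(co$expr)
    meth <- filter_and_impute(co$meth)
    rb <- summarize_regions(meth, clusters)
    idx <- instability_indices(meth, clusters, co$sheet)
    canc <- co$sheet$sample_id[co$sheet$status == "cancer"]
    idx <- idx[idx$sample_id %in% canc, ]
    pm <- promoter_methylation(rb, clusters, genes)
    recs <- full_model_causal_test(genes, expr, pm, idx)
    for (g in genes) for (ix in colnames(surv))
      surv[g, ix] <- surv[g, ix] +
        recs$survives[recs$gene == g & recs$index == ix]
  }
  n_c <- length(ds$cohorts)
  expect_gte(surv["UHRF1", "HyperZ"], n_c - 1)
  expect_gte(surv["WHSC1", "HyperZ"], n_c - 1)
  expect_gte(surv["CBX7", "HypoZ"], n_c - 1)
  expect_lt(surv["EZH2", "HyperZ"], n_c / 2)   # model B removed
  expect_lt(surv["EYA4", "HyperZ"], n_c / 2)   # model A removed

  # joint sample permutation leaves partial correlations unchanged
  co <- ds$cohorts[[1]]
  expr <- preprocess_expression(co$expr)
  meth <- filter_and_impute(co$meth)
  rb <- summarize_regions(meth, clusters)
  idx <- instability_indices(meth, clusters, co$sheet)
  canc <- co$sheet$sample_id[co$sheet$status == "cancer"]
  idx <- idx[idx$sample_id %in% canc, ]
  pm <- promoter_methylation(rb, clusters, genes)
  r1 <- full_model_causal_test(genes, expr, pm, idx)
  perm <- sample(canc)
  expr2 <- expression_matrix(expr$values[, c(setdiff(colnames(expr$values), canc),
                                             perm)], "X", "log2")
  r2 <- full_model_causal_test(genes, expr2, pm, idx)
  expect_equal(r1$r, r2$r, tolerance = 1e-10)

  expect_error(full_model_causal_test(genes, expr, pm, idx[1:10, ]),
               "insufficient samples")
})

test_that("consensus keeps only edges supported with one sign in >= m cohorts", {
  rec <- data.frame(
    gene = rep("gA", 10), cohort = paste0("C", 1:10), index = "HyperZ",
    r = c(rep(0.4, 7), rep(-0.4, 3)),
    p = c(rep(0.01, 7), rep(0.01, 3)))
  out <- build_consensus(rec, m = 6)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sign, 1L)
  expect_equal(out$n_support, 7L)

  # 4 positive + 3 negative significant: neither sign reaches 6
  rec2 <- rec[1:7, ]
  rec2$r <- c(rep(0.4, 4), rep(-0.4, 3))
  expect_equal(nrow(build_consensus(rec2, m = 6)), 0L)

  # cohort order must not matter
  out2 <- build_consensus(rec[sample(10), ], m = 6)
  expect_identical(out, out2)
})
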