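test_that("Fisher Z is strictly increasing and inverts to machine precision", {
  r <- seq(-0.99, 0.99, by = 0.01)
  z <- fisher_z(r)
  expect_true(all(diff(z) > 0))
  expect_equal(fisher_z_inv(z), r, tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
})

test_that("moderated t with d0 = 0 equals the ordinary pooled-variance t-test", {
  set.seed(14)
  v <- matrix(rnorm(20 * 12, 5, 1), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("S", 1:12)))
  sheet <- data.frame(sample_id = colnames(v),
                      status = rep(c("normal", "cancer"), each = 6),
                      cohort_id = "X")
  expr <- expression_matrix(v, "X", "log2")
  out <- moderated_t(expr, sheet, d0 = 0)
  ref <- apply(v, 1, function(row)
    t.test(row[7:12], row[1:6], var.equal = TRUE)$statistic)
  expect_equal(out$t, unname(ref), tolerance = 1e-10)

  # equal group means -> t = 0, P = 1
  v0 <- v
  v0[1, ] <- rep(c(1, 2, 3), 4)[order(rep(1:2, 6))]
  v0[1, 1:6] <- c(1, 2, 3, 1, 2, 3); v0[1, 7:12] <- c(3, 2, 1, 3, 2, 1)
  out0 <- moderated_t(expression_matrix(v0, "X", "log2"), sheet, d0 = 0)
  expect_equal(out0$t[1], 0)
  expect_equal(out0$p[1], 1)
})

test_that("moderated t has nominal type-I error and tracks limma on null genes", {
  set.seed(15)
  n_genes <- 1200
  v <- matrix(rnorm(n_genes * 30, 6, sqrt(rchisq(n_genes, 8) / 8)),
              n_genes, 30,
              dimnames = list(paste0("g", seq_len(n_genes)), paste0("S", 1:30)))
  sheet <- data.frame(sample_id = colnames(v),
                      status = rep(c("normal", "cancer"), c(10, 20)),
                      cohort_id = "X")
  out <- moderated_t(expression_matrix(v, "X", "log2"), sheet)
  fpr <- mean(out$p < 0.05)
  expect_gt(fpr, 0.03)
  expect_lt(fpr, 0.07)

  # independent cross-check: limma's moderated t on the same data
  design <- model.matrix(~ factor(sheet$status, c("normal", "cancer")))
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_gt(cor(out$t, fit$t[, 2], method = "spearman"), 0.98)
})

test_that("consistency counting splits by direction and applies the m-of-T rule", {
  rec <- data.frame(
    gene = rep(c("gA", "gB"), each = 10),
    cohort = rep(paste0("C", 1:10), 2),
    p = c(rep(0.01, 8), 0.5, 0.5,          # gA: 8 significant
          rep(0.01, 8), 0.5, 0.5),
    direction = c(rep("up", 10),
                  c(rep("up", 7), "down", "up", "up")))  # gB: 7 up + 1 down
  out <- consistency_count(rec, alpha = 0.05, m = 8)
  expect_equal(out$call[out$gene == "gA"], "up")
  expect_equal(out$n_up[out$gene == "gA"], 8L)
  expect_equal(out$call[out$gene == "gB"], "none")
  expect_equal(out$n_down[out$gene == "gB"], 1L)
})

test_that("binomial tail matches pbinom to 1e-12 and handles boundaries", {
  for (T in c(3, 5, 10, 20)) {
    for (m in 0:T) {
      for (p in c(0, 0.12, 0.32, 0.5, 0.9, 1)) {
        expect_equal(binomial_tail(T, m, p),
                     pbinom(m - 1, T, p, lower.tail = FALSE),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(binomial_tail(10, 0, 0.3), 1)
  expect_equal(binomial_tail(10, 8, 0), 0)
})

test_that("expected random counts and meta significance follow the binomial null", {
  tp <- binomial_tail(10, 8, 0.32)
  ec <- expected_random_count(212, tp)
  expect_equal(ec$expectation, 212 * tp)
  expect_equal(ec$sd, sqrt(212 * tp * (1 - tp)))
  expect_equal(expected_random_count(212, 0)$expectation, 0)
  expect_equal(expected_random_count(424, tp)$expectation, 2 * ec$expectation)

  expect_equal(meta_significance(0, 212, tp), 1)
  expect_equal(meta_significance(1, 212, tp), 1 - (1 - tp)^212,
               tolerance = 1e-12)
  expect_lt(meta_significance(35, 212, tp), 1e-40)
})

test_that("expression-index correlation records carry r, Fisher Z and the n-3 P value", {
  set.seed(33)
  n <- 30
  idx <- data.frame(sample_id = paste0("T", 1:n),
                    HyperZ_sig = runif(n, 0, 3), HypoZ_sig = runif(n, 0, 3))
  v <- rbind(match_hyper = idx$HyperZ_sig,
             noise = rnorm(n),
             anti = -idx$HyperZ_sig + rnorm(n, 0, 0.1),
             flat = rep(1, n))
  colnames(v) <- idx$sample_id
  recs <- correlate_expr_index(expression_matrix(v, "X", "log2"), idx)
  hy <- recs[recs$index == "HyperZ", ]
  expect_equal(hy$r[hy$gene == "match_hyper"], 1)
  expect_false(hy$defined[hy$gene == "match_hyper"])  # |r| = 1 -> Z infinite
  expect_true(is.na(hy$r[hy$gene == "flat"]))
  r_noise <- hy$r[hy$gene == "noise"]
  expect_equal(hy$z[hy$gene == "noise"], fisher_z(r_noise))
  expect_equal(hy$p[hy$gene == "noise"],
               2 * pnorm(-abs(fisher_z(r_noise)) * sqrt(n - 3)))
  # antisymmetry: negating the gene negates r and z
  v2 <- v; v2["anti", ] <- -v2["anti", ]
  recs2 <- correlate_expr_index(expression_matrix(v2, "X", "log2"), idx)
  hy2 <- recs2[recs2$index == "HyperZ", ]
  expect_equal(hy2$r[hy2$gene == "anti"], -hy$r[hy$gene == "anti"])
  expect_equal(hy2$z[hy2$gene == "anti"], -hy$z[hy$gene == "anti"])
})

test_that("correlation consistency applies the four-event m-of-T rule", {
  rec <- expand.grid(cohort = paste0("C", 1:10), gene = c("gA", "gB"),
                     index = c("HyperZ", "HypoZ"), stringsAsFactors = FALSE)
  rec$r <- 0.5
  rec$p <- 0.5
  sel <- rec$gene == "gA" & rec$index == "HyperZ" & rec$cohort %in% paste0("C", 1:6)
  rec$p[sel] <- 0.01                                   # gA: exactly 6 positive
  sel2 <- rec$gene == "gB" & rec$index == "HypoZ" & rec$cohort %in% paste0("C", 1:5)
  rec$p[sel2] <- 0.01; rec$r[sel2] <- -0.5             # gB: only 5 negative
  out <- correlation_consistency(rec, alpha = 0.05, m = 6)
  expect_equal(out$call[out$gene == "gA" & out$index == "HyperZ"], "positive")
  expect_equal(out$call[out$gene == "gB" & out$index == "HypoZ"], "none")
  expect_equal(out$n_neg[out$gene == "gB" & out$index == "HypoZ"], 5L)
})

test_that("expression-expression meta network keeps real co-expression and rejects noise", {
  set.seed(55)
  n <- 60
  mk_cohort <- function(cid) {
    base <- rnorm(n)
    v <- rbind(gA = base + rnorm(n, 0, 0.5),
               gB = base + rnorm(n, 0, 0.5),     # rho ~ 0.8 with gA
               gC = rnorm(n), gD = rnorm(n))     # independent
    colnames(v) <- paste0(cid, "_T", 1:n)
    list(expr = expression_matrix(v, cid, "log2"),
         sheet = data.frame(sample_id = colnames(v), status = "cancer",
                            cohort_id = cid))
  }
  cos <- lapply(paste0("C", 1:4), mk_cohort)
  net <- expr_expr_meta_network(lapply(cos, `[[`, "expr"),
                                lapply(cos, `[[`, "sheet"),
                                c("gA", "gB", "gC", "gD"))
  ab <- net[net$gene_a == "gA" & net$gene_b == "gB", ]
  expect_true(ab$edge)
  expect_equal(ab$sign, 1L)
  cd <- net[net$gene_a == "gC" & net$gene_b == "gD", ]
  expect_false(cd$edge)

  # single cohort, exactly zero correlation -> no edge
  v <- rbind(g1 = c(-1, 1, -1, 1), g2 = c(-1, -1, 1, 1))  # r = 0
  colnames(v) <- paste0("T", 1:4)
  one <- list(expr = expression_matrix(v - min(v) + 1, "C1", "log2"),
              sheet = data.frame(sample_id = colnames(v), status = "cancer",
                                 cohort_id = "C1"))
  net1 <- expr_expr_meta_network(list(one$expr), list(one$sheet), c("g1", "g2"))
  expect_false(net1$edge)
})

test_that("null probabilities average per-cohort significant fractions", {
  rec <- data.frame(gene = rep(paste0("g", 1:4), 2),
                    cohort = rep(c("C1", "C2"), each = 4),
                    p = c(0.01, 0.5, 0.5, 0.5, 0.01, 0.01, 0.5, 0.5),
                    direction = "up")
  np <- de_null_probs(rec)
  expect_equal(np$p_u, mean(c(1 / 4, 2 / 4)))
  expect_equal(np$p_d, 0)
})
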