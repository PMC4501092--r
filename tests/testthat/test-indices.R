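make_ann <- function(pos, class = "cgi", chrom = "chr1",
                     promoter = rep(NA_character_, length(pos))) {
  data.frame(probe_id = sprintf("p%03d", seq_along(pos)), chromosome = chrom,
             position = as.integer(pos), region_class = class,
             promoter_gene = promoter, promoter_cgi = class == "cgi",
             stringsAsFactors = FALSE)
}

test_that("greedy bounded clustering reproduces the hand traces", {
  cs <- cluster_probes(make_ann(c(100, 300, 900, 2600)))
  sizes <- vapply(cs$members, length, 0L)
  expect_equal(unname(sizes), c(2L, 1L, 1L))
  expect_equal(cs$members[[1]], c("p001", "p002"))
  expect_equal(cs$clusters$span, c(200L, 0L, 0L))

  # span cap: gaps all 400 but width bound splits after 1300
  cs2 <- cluster_probes(make_ann(c(100, 500, 900, 1300, 1700)))
  expect_equal(unname(vapply(cs2$members, length, 0L)), c(4L, 1L))
  expect_equal(cs2$clusters$span[1], 1200L)

  # singleton
  cs3 <- cluster_probes(make_ann(42))
  expect_equal(nrow(cs3$clusters), 1L)
  expect_equal(cs3$clusters$span, 0L)
})

test_that("clusters never mix chromosomes or region classes and respect both bounds", {
  set.seed(11)
  ann <- rbind(make_ann(sort(sample(1:20000, 40)), "cgi", "chr1"),
               make_ann(sort(sample(1:20000, 40)), "opensea", "chr2"))
  ann$probe_id <- sprintf("q%03d", seq_len(nrow(ann)))
  cs <- cluster_probes(ann)
  for (i in seq_len(nrow(cs$clusters))) {
    probes <- ann[match(cs$members[[i]], ann$probe_id), ]
    expect_equal(length(unique(probes$chromosome)), 1L)
    expect_equal(length(unique(probes$region_class)), 1L)
    expect_lte(max(probes$position) - min(probes$position), 1500)
    if (nrow(probes) > 1) expect_lte(max(diff(sort(probes$position))), 500)
  }
})

test_that("region summarization averages member-probe betas", {
  ann <- make_ann(c(100, 200, 5000))
  cs <- cluster_probes(ann)
  b <- rbind(p001 = c(0.2, 0.6), p002 = c(0.4, 0.8), p003 = c(0.5, 0.5))
  colnames(b) <- c("S1", "S2")
  rb <- summarize_regions(methylation_matrix(b, "X"), cs)
  expect_equal(unname(rb[1, ]), c(0.3, 0.7))   # mean of the pair
  expect_equal(unname(rb[2, ]), c(0.5, 0.5))   # singleton = probe beta

  bna <- b; bna[1, 1] <- NA
  expect_error(summarize_regions(methylation_matrix(bna, "X"), cs), "complete")
})

test_that("z-scores use the normal reference with sample sd and flag degenerate clusters", {
  f <- worked_fixture()
  cs <- cluster_probes(f$annotation)
  rb <- summarize_regions(f$meth, cs)
  z <- compute_zscores(rb, f$sheet)
  expect_equal(z$reference$mu, c(0.10, 0.10))
  expect_equal(z$reference$sd, rep(0.0163299, 2), tolerance = 1e-5)
  expect_equal(unname(z$z[, "T1"]), c(12.2474, -1), tolerance = 1e-3)
  expect_equal(unname(z$z[, "T2"]), c(0, 0))

  # constant normal reference is excluded
  b2 <- rbind(c1 = c(0.5, 0.5, 0.5, 0.5, 0.9, 0.2),
              c2 = c(0.1, 0.2, 0.1, 0.2, 0.5, 0.1))
  colnames(b2) <- f$sheet$sample_id
  z2 <- compute_zscores(b2, f$sheet)
  expect_equal(z2$excluded, "c1")
  expect_equal(rownames(z2$z), "c2")

  expect_error(compute_zscores(rb, f$sheet[c(1, 5, 6), ]), "cover")
})

test_that("HyperZ/HypoZ match the fixture arithmetic and the Heaviside rule", {
  f <- worked_fixture()
  cs <- cluster_probes(f$annotation)
  z <- compute_zscores(summarize_regions(f$meth, cs), f$sheet)
  expect_error(compute_indices(z, cs), "open-sea")  # fixture is CGI-only

  # two CGI clusters z = {12.247, -1} -> HyperZ = 12.247/2; z = 0 -> 0 (H(0)=0)
  ann2 <- rbind(f$annotation,
                make_ann(c(100, 7000), "opensea", "chrS"))
  ann2$probe_id[3:4] <- c("os1", "os2")
  b <- rbind(f$meth$betas,
             os1 = c(0.8, 0.82, 0.78, 0.8, 0.8 - 4 * sd(c(0.8, 0.82, 0.78, 0.8)),
                     0.8),
             os2 = c(0.8, 0.82, 0.78, 0.8, 0.8 + 2 * sd(c(0.8, 0.82, 0.78, 0.8)),
                     0.8))
  cs2 <- cluster_probes(ann2)
  z2 <- compute_zscores(summarize_regions(methylation_matrix(b, "FIX"), cs2),
                        f$sheet)
  idx <- compute_indices(z2, cs2, "all")
  t1 <- idx[idx$sample_id == "T1", ]
  expect_equal(t1$HyperZ, 12.2474 / 2, tolerance = 1e-3)
  expect_equal(t1$HypoZ, (4 + 0) / 2, tolerance = 1e-6)  # z = {-4, +2}
  t2 <- idx[idx$sample_id == "T2", ]
  expect_equal(t2$HyperZ, 0)
  expect_equal(t2$HypoZ, 0)
  expect_true(all(idx$HyperZ >= 0 & idx$HypoZ >= 0))

  # significant variant: per-sample denominator over |z| > 1.645 clusters only
  sig <- compute_indices(z2, cs2, "significant")
  s1 <- sig[sig$sample_id == "T1", ]
  expect_equal(s1$HyperZ, 12.2474, tolerance = 1e-3)  # only cluster 1 counts
  expect_equal(s1$n_hyper, 1L)
  expect_equal(s1$HypoZ, 4, tolerance = 1e-6)
  expect_equal(sig[sig$sample_id == "T2", "HyperZ"], 0)  # none significant
})

test_that("adding a positive shift to cancer CGI betas strictly increases HyperZ", {
  ds <- small_sim()
  co <- ds$cohorts[[1]]
  clusters <- cluster_probes(ds$annotation)
  meth <- filter_and_impute(co$meth)
  idx1 <- instability_indices(meth, clusters, co$sheet)
  b2 <- meth$betas
  cgi <- ds$annotation$probe_id[ds$annotation$region_class == "cgi"]
  canc <- co$sheet$sample_id[co$sheet$status == "cancer"]
  b2[cgi, canc] <- pmin(b2[cgi, canc] + 0.05, 0.999)
  idx2 <- instability_indices(methylation_matrix(b2, "X"), clusters, co$sheet)
  canc_rows <- idx1$sample_id %in% canc
  expect_true(all(idx2$HyperZ[canc_rows] > idx1$HyperZ[canc_rows]))
})

test_that("normals' leave-one-out indices are small relative to cancers", {
  ds <- small_sim()
  co <- ds$cohorts[[1]]
  clusters <- cluster_probes(ds$annotation)
  meth <- filter_and_impute(co$meth)
  idx <- instability_indices(meth, clusters, co$sheet)
  canc <- co$sheet$sample_id[co$sheet$status == "cancer"]
  med_cancer <- median(idx$HyperZ[idx$sample_id %in% canc])
  # score each normal against the remaining normals
  norm_ids <- co$sheet$sample_id[co$sheet$status == "normal"]
  loo <- vapply(norm_ids, function(nid) {
    sh <- co$sheet
    sh$status[sh$sample_id == nid] <- "cancer"
    sh <- sh[sh$status == "normal" | sh$sample_id == nid, ]
    keep <- sh$sample_id
    m <- methylation_matrix(meth$betas[, keep, drop = FALSE], "X")
    instability_indices(m, clusters, sh)$HyperZ
  }, 0)
  expect_lt(median(loo), 0.2 * med_cancer)
})

test_that("index association reports Spearman, P and R^2 with degenerate handling", {
  tbl <- data.frame(HyperZ = c(1, 2, 3, 4), HypoZ = c(1, 2, 3, 4))
  a <- index_association(tbl)
  expect_equal(a$rho, 1)
  expect_equal(a$r_squared, 1)

  tbl2 <- data.frame(HyperZ = c(1, 2, 3, 4), HypoZ = c(9, 7, 5, 1))
  expect_equal(index_association(tbl2)$rho, -1)

  tbl3 <- data.frame(HyperZ = c(1, 1, 1), HypoZ = c(1, 2, 3))
  expect_true(is.na(index_association(tbl3)$rho))
  expect_error(index_association(tbl3[1:2, ]), ">= 3")
})
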