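#' Per-locus correlation of region methylation with a regulator's expression
#'
#' For every eligible regional cluster, the Pearson correlation between its
#' beta values and the given gene's log2 expression over cancer samples is
#' computed and Fisher-transformed. For hypermethylation-associated
#' regulators only CGI clusters are considered; for hypomethylation-associated
#' regulators only open-sea clusters.
#'
#' @param region_betas clusters x samples matrix (all samples of the cohort).
#' @param expr log2 \code{ExpressionMatrix}.
#' @param gene regulator gene symbol.
#' @param clusters \code{RegionalClusterSet}.
#' @param sheet sample sheet (cancer samples are used).
#' @param class_restriction \code{"cgi"} or \code{"opensea"}.
#' @return data.frame: cluster_id, cohort, gene, region_class, r, z, n;
#'   zero-variance clusters get NA r/z.
#' @export
locus_correlations <- function(region_betas, expr, gene, clusters, sheet,
                               class_restriction = c("cgi", "opensea")) {
  class_restriction <- match.arg(class_restriction)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!gene %in% rownames(expr$values))
    stop("gene not in expression matrix: ", gene)
  sheet <- validate_sample_sheet(sheet)
  canc <- sheet$sample_id[sheet$status == "cancer"]
  samples <- intersect(intersect(colnames(region_betas), colnames(expr$values)),
                       canc)
  if (length(samples) < 4) stop("need >= 4 matched cancer samples")
  info <- clusters$clusters
  elig <- info$cluster_id[info$region_class == class_restriction]
  elig <- intersect(elig, rownames(region_betas))
  rb <- region_betas[elig, samples, drop = FALSE]
  ev <- expr$values[gene, samples]
  rsd <- apply(rb, 1, stats::sd)
  r <- rep(NA_real_, length(elig))
  if (stats::sd(ev) > 0 && any(rsd > 0))
    r[rsd > 0] <- as.vector(stats::cor(t(rb[rsd > 0, , drop = FALSE]), ev))
  data.frame(cluster_id = elig, cohort = expr$cohort_id, gene = gene,
             region_class = class_restriction, r = r, z = fisher_z(r),
             n = length(samples), stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-cohort rank consistency of locus correlation statistics
#'
#' Clusters are ranked by the reference cohort's Fisher Z (descending for
#' positively associated regulators, ascending for negative); the Spearman
#' correlation between the reference statistics and each other cohort's
#' statistics over the shared clusters measures whether the same loci are
#' affected across cancer types. Average ranks are used for ties, so the
#' result is invariant to strictly monotone transforms of either cohort's
#' statistics.
#'
#' @param tables list of \code{\link{locus_correlations}} outputs, one per
#'   cohort, named by cohort.
#' @param reference name (or position) of the reference cohort.
#' @param direction \code{"descending"} or \code{"ascending"} reference order.
#' @return list with \code{ranking} (data.frame cluster_id, reference z, rank)
#'   and \code{report} (data.frame cohort, rho, p).
#' @export
rank_consistency <- function(tables, reference = 1,
                             direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$cohort[1], "")
  if (is.numeric(reference)) reference <- names(tables)[reference]
  if (!reference %in% names(tables)) stop("unknown reference cohort: ", reference)
  shared <- Reduce(intersect, lapply(tables, function(t)
    t$cluster_id[!is.na(t$z)]))
  if (length(shared) < 3) stop("fewer than 3 clusters shared across cohorts")
  ref <- tables[[reference]]
  zr <- ref$z[match(shared, ref$cluster_id)]
  ord <- order(zr, decreasing = (direction == "descending"))
  ranking <- data.frame(cluster_id = shared[ord], z_reference = zr[ord],
                        rank = seq_along(shared), stringsAsFactors = FALSE)
  others <- setdiff(names(tables), reference)
  rows <- lapply(others, function(cn) {
    t <- tables[[cn]]
    zo <- t$z[match(shared, t$cluster_id)]
    ct <- suppressWarnings(stats::cor.test(zr, zo, method = "spearman",
                                           exact = FALSE))
    data.frame(cohort = cn, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(ranking = ranking, report = report, reference = reference)
}
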