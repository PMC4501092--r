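#' Partial correlation with a covariate set
#'
#' Pearson correlation between the residuals of \code{y} and \code{x} after
#' least-squares regression on the covariates (plus an intercept). Covariates
#' are standardized before regression for numerical stability (identical
#' results in exact arithmetic); collinear covariates are dropped to an
#' independent subset by rank-revealing (pivoted) QR, with the reduction
#' reported. The P value uses the Fisher Z normal approximation with variance
#' 1/(n - k - 3), k = number of retained covariates.
#'
#' @param y,x numeric sample vectors of equal length, no missing values.
#' @param covariates numeric matrix (samples x covariates), data.frame or
#'   NULL/empty for a plain Pearson correlation.
#' @return list: \code{r}, \code{p}, \code{n}, \code{k} (retained covariates),
#'   \code{dropped} (number of collinear covariates removed).
#' @export
partial_correlation <- function(y, x, covariates = NULL) {
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  stopifnot(length(x) == n)
  if (anyNA(y) || anyNA(x)) stop("missing values are not allowed")
  dropped <- 0L
  if (is.null(covariates) || NCOL(covariates) == 0 || NROW(covariates) == 0) {
    k <- 0L
    ry <- y - mean(y)
    rx <- x - mean(x)
  } else {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates must have one row per sample")
    if (anyNA(C)) stop("missing values are not allowed")
    csd <- apply(C, 2, stats::sd)
    C <- C[, csd > 0, drop = FALSE]
    dropped <- dropped + sum(csd == 0)
    if (ncol(C)) C <- scale(C)
    X <- cbind(1, C)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- dropped + (ncol(X) - qrX$rank)
      X <- X[, sort(keep), drop = FALSE]
      qrX <- qr(X)
    }
    k <- ncol(X) - 1L
    if (n <= k + 2) stop("need n > number of covariates + 2 (n = ", n,
                         ", k = ", k, ")")
    ry <- qr.resid(qrX, y)
    rx <- qr.resid(qrX, x)
  }
  if (stats::sd(ry) == 0 || stats::sd(rx) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, k = k, dropped = dropped))
  r <- stats::cor(ry, rx)
  df_z <- n - k - 3
  p <- if (abs(r) >= 1) 0
       else if (df_z > 0) 2 * stats::pnorm(-abs(fisher_z(r)) * sqrt(df_z))
       else NA_real_
  list(r = r, p = p, n = n, k = k, dropped = dropped)
}

#' Single-gene causal test: index vs expression given own promoter methylation
#'
#' Partial correlation between a gene's expression and each instability index
#' with the gene's own promoter methylation as the only covariate. A gene
#' "survives" for an index when the partial P < alpha and the partial sign
#' equals the marginal sign - i.e., its promoter methylation cannot explain
#' the marginal association (model C), as opposed to the promoter-confounded
#' model A.
#'
#' @param gene gene symbol.
#' @param expr log2 \code{ExpressionMatrix}.
#' @param promoter_meth named numeric vector: the gene's promoter-cluster mean
#'   beta per sample (NULL if the gene has no promoter cluster).
#' @param indices index table (cancer samples), as in
#'   \code{\link{correlate_expr_index}}.
#' @param variant which index variant columns to use.
#' @param alpha significance level.
#' @return data.frame, one row per index: gene, index, mode, marginal_r,
#'   r, p, k, n, survives, testable.
#' @export
single_gene_causal_test <- function(gene, expr, promoter_meth, indices,
                                    variant = c("significant", "all"),
                                    alpha = 0.05) {
  variant <- match.arg(variant)
  cols <- if (variant == "significant") c(HyperZ = "HyperZ_sig", HypoZ = "HypoZ_sig")
          else c(HyperZ = "HyperZ", HypoZ = "HypoZ")
  if (!gene %in% rownames(expr$values)) stop("gene not in expression matrix: ", gene)
  samples <- intersect(colnames(expr$values), indices$sample_id)
  if (!is.null(promoter_meth))
    samples <- intersect(samples, names(promoter_meth))
  ev <- expr$values[gene, samples]
  idx <- indices[match(samples, indices$sample_id), , drop = FALSE]
  rows <- lapply(names(cols), function(ix) {
    yv <- idx[[cols[[ix]]]]
    marg <- partial_correlation(yv, ev, NULL)
    if (is.null(promoter_meth)) {
      return(data.frame(gene = gene, cohort = expr$cohort_id, index = ix,
                        mode = "single_gene", marginal_r = marg$r,
                        r = NA_real_, p = NA_real_, k = NA_integer_,
                        n = length(samples), survives = FALSE,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    pc <- partial_correlation(yv, ev, promoter_meth[samples])
    surv <- !is.na(pc$p) && pc$p < alpha && !is.na(marg$r) &&
      sign(pc$r) == sign(marg$r)
    data.frame(gene = gene, cohort = expr$cohort_id, index = ix,
               mode = "single_gene", marginal_r = marg$r, r = pc$r, p = pc$p,
               k = pc$k, n = pc$n, survives = surv, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full-model causal test over a selected gene set
#'
#' For each of the K selected genes, the partial correlation between its
#' expression and each index is computed with the other K-1 genes' expression
#' plus all K genes' promoter methylation levels as covariates. A gene
#' surviving here associates with the index independently of both its own
#' promoter methylation and the other candidates (model C), whereas a
#' passenger merely correlated with a driver (model B) is silenced.
#'
#' @param genes character vector of K gene symbols.
#' @param expr log2 \code{ExpressionMatrix}.
#' @param promoter_meth matrix genes x samples of promoter-cluster mean betas
#'   (rows may cover a subset of \code{genes}; missing rows are dropped from
#'   the covariate set with a message).
#' @param indices index table (cancer samples).
#' @param variant index variant.
#' @param alpha significance level.
#' @return data.frame, one row per gene x index, columns as in
#'   \code{\link{single_gene_causal_test}} with mode \code{"full_model"}.
#' @export
full_model_causal_test <- function(genes, expr, promoter_meth, indices,
                                   variant = c("significant", "all"),
                                   alpha = 0.05) {
  variant <- match.arg(variant)
  cols <- if (variant == "significant") c(HyperZ = "HyperZ_sig", HypoZ = "HypoZ_sig")
          else c(HyperZ = "HyperZ", HypoZ = "HypoZ")
  genes <- intersect(genes, rownames(expr$values))
  K <- length(genes)
  samples <- intersect(colnames(expr$values), indices$sample_id)
  pm_genes <- intersect(genes, rownames(promoter_meth))
  if (length(pm_genes) < K)
    message("no promoter methylation for: ",
            paste(setdiff(genes, pm_genes), collapse = ", "))
  if (length(pm_genes))
    samples <- intersect(samples, colnames(promoter_meth))
  n <- length(samples)
  n_cov <- (K - 1) + length(pm_genes)
  if (n <= n_cov + 2)
    stop("insufficient samples for the full model: need n > ", n_cov + 2,
         ", have ", n)
  E <- expr$values[genes, samples, drop = FALSE]
  PM <- if (length(pm_genes)) promoter_meth[pm_genes, samples, drop = FALSE]
        else NULL
  idx <- indices[match(samples, indices$sample_id), , drop = FALSE]
  rows <- list()
  for (g in genes) {
    others <- setdiff(genes, g)
    cov <- t(rbind(E[others, , drop = FALSE], PM))
    for (ix in names(cols)) {
      yv <- idx[[cols[[ix]]]]
      marg <- partial_correlation(yv, E[g, ], NULL)
      pc <- partial_correlation(yv, E[g, ], cov)
      surv <- !is.na(pc$p) && pc$p < alpha && !is.na(marg$r) &&
        sign(pc$r) == sign(marg$r)
      rows[[paste(g, ix)]] <- data.frame(
        gene = g, cohort = expr$cohort_id, index = ix, mode = "full_model",
        marginal_r = marg$r, r = pc$r, p = pc$p, k = pc$k, n = pc$n,
        survives = surv, testable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus gene-index network across cohorts
#'
#' An edge (gene, index, sign) is kept iff at least \code{m} cohorts show a
#' partial correlation with P < alpha and that sign.
#'
#' @param records row-bound causal-test records across cohorts (any mode; one
#'   mode at a time is recommended).
#' @param alpha significance level.
#' @param m consistency threshold (default 6 of 10).
#' @return data.frame: gene, index, sign (+1/-1), n_support.
#' @export
build_consensus <- function(records, alpha = 0.05, m = 6) {
  sig <- !is.na(records$p) & records$p < alpha
  key <- paste(records$gene, records$index, sep = "\r")
  pos <- tapply(sig & records$r > 0, key, sum)
  neg <- tapply(sig & records$r < 0, key, sum)
  keys <- sort(unique(key))
  pos <- pos[keys]; neg <- neg[keys]
  keep_pos <- !is.na(pos) & pos >= m
  keep_neg <- !is.na(neg) & neg >= m
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- rbind(
    if (any(keep_pos)) data.frame(gene = parts[keep_pos, 1],
                                  index = parts[keep_pos, 2], sign = 1L,
                                  n_support = as.integer(pos[keep_pos]),
                                  stringsAsFactors = FALSE),
    if (any(keep_neg)) data.frame(gene = parts[keep_neg, 1],
                                  index = parts[keep_neg, 2], sign = -1L,
                                  n_support = as.integer(neg[keep_neg]),
                                  stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(gene = character(0), index = character(0),
                      sign = integer(0), n_support = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter methylation levels of genes from regional clusters
#'
#' The promoter methylation level of a gene is the mean region beta of the
#' promoter-CGI cluster(s) annotated to it (averaged if several).
#'
#' @param region_betas clusters x samples matrix.
#' @param clusters \code{RegionalClusterSet} with \code{promoter_gene} filled.
#' @param genes gene symbols to extract.
#' @return matrix genes x samples (genes without a promoter cluster omitted).
#' @export
promoter_methylation <- function(region_betas, clusters, genes) {
  info <- clusters$clusters
  rows <- lapply(genes, function(g) {
    cl <- info$cluster_id[!is.na(info$promoter_gene) & info$promoter_gene == g &
                            info$promoter_cgi]
    cl <- intersect(cl, rownames(region_betas))
    if (!length(cl)) return(NULL)
    colMeans(region_betas[cl, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, TRUE)
  if (!any(keep))
    return(matrix(numeric(0), 0, ncol(region_betas),
                  dimnames = list(NULL, colnames(region_betas))))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- genes[keep]
  out
}
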