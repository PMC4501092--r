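#' Beta value from methylated/unmethylated intensities
#'
#' beta = Max(M,0) / (Max(M,0) + Max(U,0) + 100). Negative intensities are
#' clamped to zero by the formula itself; the +100 offset keeps the result in
#' [0, 1).
#'
#' @param M methylated-allele intensity (vectorized).
#' @param U unmethylated-allele intensity (vectorized).
#' @return beta values in [0, 1).
#' @export
beta_from_intensities <- function(M, U) {
  if (!all(is.finite(M)) || !all(is.finite(U)))
    stop("intensities must be finite")
  m <- pmax(M, 0)
  u <- pmax(U, 0)
  m / (m + u + 100)
}

#' Preprocess a raw expression matrix to log2 scale
#'
#' Zero entries are replaced by the minimal positive value of the whole
#' dataset, then every entry is log2-transformed.
#'
#' @param expr raw-scale \code{\link{expression_matrix}}.
#' @return log2-scale \code{ExpressionMatrix}.
#' @export
preprocess_expression <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "raw") stop("expression matrix is already on log2 scale")
  v <- expr$values
  pos <- v[v > 0]
  if (!length(pos)) stop("all-zero expression matrix cannot be log-transformed")
  v[v == 0] <- min(pos)
  expression_matrix(log2(v), expr$cohort_id, scale = "log2")
}

#' Drop high-missingness probes and impute the rest by probe-wise KNN
#'
#' Probes missing in more than \code{max_na_fraction} of samples are removed.
#' Each remaining NA is filled with the average, over the \code{k} probes
#' nearest in Euclidean distance (computed on samples where both probes are
#' observed, normalized by the overlap size), of those probes' betas in the
#' missing sample; imputed values are clipped to [0,1]. If no neighbor is
#' observed in that sample the probe mean is used and a warning is issued.
#' Observed values are never altered.
#'
#' @param meth \code{\link{methylation_matrix}}.
#' @param max_na_fraction probe NA-fraction threshold (default 0.70).
#' @param k number of neighbors (default 10).
#' @return complete \code{MethylationMatrix}; attribute \code{"n_dropped"}
#'   records the number of removed probes.
#' @export
filter_and_impute <- function(meth, max_na_fraction = 0.70, k = 10) {
  stopifnot(inherits(meth, "MethylationMatrix"))
  b <- meth$betas
  na_frac <- rowMeans(is.na(b))
  if (all(na_frac > max_na_fraction))
    stop("no probe passes the missingness threshold")
  drop_n <- sum(na_frac > max_na_fraction)
  b <- b[na_frac <= max_na_fraction, , drop = FALSE]
  if (anyNA(b)) b <- .knn_impute(b, k)
  out <- methylation_matrix(b, meth$cohort_id)
  attr(out, "n_dropped") <- drop_n
  out
}

# Pairwise mean-squared differences over shared observed samples via masked
# cross-products, then probe-wise KNN fill.
.knn_impute <- function(b, k) {
  obs <- !is.na(b)
  x0 <- b
  x0[!obs] <- 0
  mm <- obs + 0
  sq <- x0^2
  cross <- tcrossprod(x0)                 # sum over shared samples of x_i x_j
  si <- sq %*% t(mm)                      # sum of x_i^2 where j observed
  overlap <- tcrossprod(mm)
  d2 <- (si + t(si) - 2 * cross) / overlap
  d2[overlap == 0] <- Inf
  diag(d2) <- Inf
  need <- which(rowSums(!obs) > 0)
  fellback <- FALSE
  for (i in need) {
    ord <- order(d2[i, ])
    miss_s <- which(!obs[i, ])
    for (s in miss_s) {
      cand <- ord[obs[ord, s] & is.finite(d2[i, ord])]
      if (length(cand)) {
        nb <- cand[seq_len(min(k, length(cand)))]
        b[i, s] <- mean(b[nb, s])
      } else {
        b[i, s] <- mean(b[i, ], na.rm = TRUE)
        fellback <- TRUE
      }
    }
  }
  if (fellback)
    warning("some missing cells had no observed neighbor; probe mean used")
  pmin(pmax(b, 0), 1)
}

#' SVD quality control with a random-matrix significance criterion
#'
#' Rows (genes or probes) are centered and variance-rescaled, the matrix is
#' decomposed by SVD, and components whose eigenvalue exceeds the
#' Marchenko-Pastur upper edge (1 + sqrt(p/n))^2 are deemed significant. Each
#' significant component's sample scores are tested for association with the
#' supplied factors: Wilcoxon rank-sum for 2-level factors, Kruskal-Wallis for
#' unordered factors with more levels, Spearman rank correlation for numeric
#' factors.
#'
#' @param mat numeric matrix, features x samples (>= 5 samples).
#' @param factors data.frame of per-sample factors (e.g., columns of a sample
#'   sheet such as \code{status}), or NULL.
#' @return list with \code{n_significant}, \code{variance_fraction} (per
#'   retained component), and \code{pvalues} (components x factors matrix).
#' @export
svd_qc <- function(mat, factors = NULL) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  p <- nrow(mat)
  if (n < 5) stop("svd_qc needs at least 5 samples")
  x <- mat - rowMeans(mat)
  rsd <- sqrt(rowSums(x^2) / (n - 1))
  keep <- rsd > 0
  nf <- if (is.null(factors)) 0L else ncol(as.data.frame(factors))
  empty <- list(n_significant = 0L, variance_fraction = numeric(0),
                pvalues = matrix(numeric(0), 0, nf,
                                 dimnames = list(NULL, names(factors))))
  if (!any(keep)) return(empty)
  x <- x[keep, , drop = FALSE] / rsd[keep]
  p <- nrow(x)
  sv <- svd(x, nu = 0, nv = min(p, n))
  lambda <- sv$d^2 / n
  edge <- (1 + sqrt(p / n))^2
  nsig <- sum(lambda > edge)
  if (nsig == 0) return(empty)
  varfrac <- (sv$d^2 / sum(sv$d^2))[seq_len(nsig)]
  pv <- NULL
  if (!is.null(factors)) {
    factors <- as.data.frame(factors)
    pv <- matrix(NA_real_, nsig, ncol(factors),
                 dimnames = list(paste0("PC", seq_len(nsig)), names(factors)))
    for (j in seq_along(factors)) {
      f <- factors[[j]]
      for (i in seq_len(nsig)) {
        sc <- sv$v[, i]
        pv[i, j] <- tryCatch({
          if (is.numeric(f)) {
            stats::cor.test(sc, f, method = "spearman", exact = FALSE)$p.value
          } else {
            f2 <- factor(f)
            if (nlevels(f2) < 2) NA_real_
            else if (nlevels(f2) == 2)
              stats::wilcox.test(sc ~ f2, exact = FALSE)$p.value
            else stats::kruskal.test(sc, f2)$p.value
          }
        }, error = function(e) NA_real_)
      }
    }
  }
  list(n_significant = nsig, variance_fraction = varfrac, pvalues = pv)
}
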