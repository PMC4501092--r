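#' Fisher Z transform and its inverse
#'
#' Z = 0.5 * log((1 + r) / (1 - r)); the variance-stabilizing transform of a
#' Pearson correlation. Under independence Z * sqrt(n - 3) is approximately
#' standard normal.
#'
#' @param r Pearson correlation(s), |r| <= 1 (|r| = 1 maps to +-Inf).
#' @return Fisher Z value(s).
#' @export
fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

#' @rdname fisher_z
#' @param z Fisher Z value(s).
#' @export
fisher_z_inv <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)

#' Moderated two-group t-tests (empirical-Bayes variance shrinkage)
#'
#' Per-gene two-group comparison (cancer - normal) on log2 expression. Gene
#' variances are shrunk toward a prior s0^2 with prior degrees of freedom d0:
#' s_tilde^2 = (d0 * s0^2 + dg * sg^2) / (d0 + dg), where sg^2 is the pooled
#' two-group variance with dg = n1 + n2 - 2 residual df. The hyperparameters
#' are estimated by closed-form moment matching of a scaled-F marginal to the
#' observed variance distribution; t = dmean / (s_tilde * sqrt(1/n1 + 1/n2))
#' is referred to a t distribution on dg + d0 df. With \code{d0 = 0} this is
#' the ordinary pooled-variance t-test.
#'
#' @param expr log2-scale \code{\link{expression_matrix}}.
#' @param sheet sample sheet with \code{status} in \{normal, cancer\};
#'   all cancer samples are used, not only those matched to methylation.
#' @param d0 optional prior df override (NULL = estimate; 0 = ordinary t).
#' @return data.frame: gene, cohort, diff (mean log2 cancer - normal),
#'   t, p, direction; attributes \code{d0}, \code{s0_2}.
#' @export
moderated_t <- function(expr, sheet, d0 = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2") stop("moderated_t expects log2-scale expression")
  sheet <- validate_sample_sheet(sheet)
  v <- expr$values
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  g1 <- sheet$status == "normal"
  g2 <- sheet$status == "cancer"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  dg <- n1 + n2 - 2
  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, g2, drop = FALSE])
  v1 <- rowSums((v[, g1, drop = FALSE] - m1)^2)
  v2 <- rowSums((v[, g2, drop = FALSE] - m2)^2)
  s2 <- (v1 + v2) / dg
  hp <- .fit_inv_chisq(s2, dg, d0)
  d0 <- hp$d0; s0_2 <- hp$s0_2
  s_tilde2 <- if (is.infinite(d0)) rep(s0_2, length(s2))
              else (d0 * s0_2 + dg * s2) / (d0 + dg)
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  diff <- m2 - m1
  t <- ifelse(se > 0, diff / se, 0)
  df <- min(dg + d0, 1e6)
  p <- 2 * stats::pt(-abs(t), df = df)
  out <- data.frame(gene = rownames(v), cohort = expr$cohort_id, diff = diff,
                    t = t, p = p,
                    direction = ifelse(diff >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# Moment matching of a scaled-F marginal: if sg^2 ~ s0^2 * F(dg, d0), then
# mean = s0^2 * d0/(d0-2) and var/mean^2 = 2 (dg + d0 - 2) / (dg (d0 - 4)).
# Excess dispersion beyond the pure chi-square ratio 2/dg determines d0.
.fit_inv_chisq <- function(s2, dg, d0 = NULL) {
  if (!is.null(d0)) {
    if (d0 == 0) return(list(d0 = 0, s0_2 = stats::median(s2)))
  }
  m <- mean(s2)
  rho <- stats::var(s2) / m^2
  if (is.null(d0)) {
    if (!is.finite(rho) || rho * dg <= 2) {
      d0 <- Inf
    } else {
      d0 <- (4 - 2 * dg - 4 * rho * dg) / (2 - rho * dg)
      if (!is.finite(d0) || d0 <= 0) d0 <- Inf
    }
  }
  s0_2 <- if (is.infinite(d0)) m else if (d0 > 2) m * (d0 - 2) / d0
          else stats::median(s2)
  list(d0 = d0, s0_2 = s0_2)
}

#' Cross-cohort consistency counting of differential expression
#'
#' Counts, per gene, the cohorts in which it is significantly up- or
#' down-regulated at nominal level \code{alpha}; a gene is called consistent
#' if at least \code{m} cohorts agree in direction.
#'
#' @param records row-bound \code{\link{moderated_t}} outputs across cohorts.
#' @param alpha nominal per-cohort significance level (default 0.05).
#' @param m consistency threshold (default 8 of 10).
#' @return data.frame: gene, n_up, n_down, call (\code{up}/\code{down}/\code{none}).
#' @export
consistency_count <- function(records, alpha = 0.05, m = 8) {
  sig <- records$p < alpha
  up <- tapply(sig & records$direction == "up", records$gene, sum)
  dn <- tapply(sig & records$direction == "down", records$gene, sum)
  genes <- names(up)
  call <- ifelse(up >= m, "up", ifelse(dn >= m, "down", "none"))
  data.frame(gene = genes, n_up = as.integer(up), n_down = as.integer(dn),
             call = unname(call), stringsAsFactors = FALSE, row.names = NULL)
}

#' Binomial upper-tail probability (explicit formula)
#'
#' P(X >= m) for X ~ Binomial(T, p), computed as the explicit sum
#' sum_{k=m}^{T} choose(T,k) p^k (1-p)^(T-k) - the analytic null for a gene
#' being significant in at least m of T independent cohorts by chance.
#'
#' @param T number of cohorts.
#' @param m consistency threshold.
#' @param p per-cohort null event probability.
#' @return exact tail probability.
#' @export
binomial_tail <- function(T, m, p) {
  stopifnot(m >= 0, m <= T, p >= 0, p <= 1)
  k <- m:T
  sum(choose(T, k) * p^k * (1 - p)^(T - k))
}

#' Expected number of null genes passing the consistency threshold
#'
#' For a pool of \code{pool} genes each passing independently with probability
#' \code{tail_p}, the count is Binomial(pool, tail_p).
#'
#' @param pool pool size (default 212, the EE gene list size).
#' @param tail_p per-gene tail probability from \code{\link{binomial_tail}}.
#' @return list with \code{expectation} and \code{sd}.
#' @export
expected_random_count <- function(pool = 212, tail_p) {
  stopifnot(tail_p >= 0, tail_p <= 1)
  list(expectation = pool * tail_p, sd = sqrt(pool * tail_p * (1 - tail_p)))
}

#' Meta-analysis significance of an observed consistent-gene count
#'
#' Exact binomial upper tail P(X >= observed), X ~ Binomial(pool, tail_p).
#'
#' @param observed observed number of consistent genes.
#' @param pool pool size.
#' @param tail_p per-gene null tail probability.
#' @return upper-tail P value.
#' @export
meta_significance <- function(observed, pool = 212, tail_p) {
  stopifnot(observed >= 0, observed <= pool)
  if (observed == 0) return(1)
  stats::pbinom(observed - 1, pool, tail_p, lower.tail = FALSE)
}

#' Average per-cohort null probabilities of differential expression
#'
#' Fraction of all genes significantly up (down) per cohort at level
#' \code{alpha}, averaged over cohorts - the empirical analogues of the
#' binomial-null event probabilities.
#'
#' @param records row-bound \code{\link{moderated_t}} outputs.
#' @param alpha nominal level.
#' @return list with \code{p_u}, \code{p_d} and the per-cohort fractions.
#' @export
de_null_probs <- function(records, alpha = 0.05) {
  sig <- records$p < alpha
  fu <- tapply(sig & records$direction == "up", records$cohort, mean)
  fd <- tapply(sig & records$direction == "down", records$cohort, mean)
  list(p_u = mean(fu), p_d = mean(fd), per_cohort_up = fu, per_cohort_down = fd)
}

#' Pearson correlation of gene expression with instability indices
#'
#' For each gene and each index (HyperZ, HypoZ; significant variant by
#' default), the Pearson correlation over matched cancer samples only is
#' transformed to a Fisher Z and a two-sided P value from the normal
#' approximation with variance 1/(n-3).
#'
#' @param expr log2-scale \code{\link{expression_matrix}}.
#' @param indices index table from \code{\link{instability_indices}} (rows =
#'   cancer samples).
#' @param variant \code{"significant"} (columns HyperZ_sig/HypoZ_sig) or
#'   \code{"all"}.
#' @return data.frame: gene, cohort, index, r, z, p, n, defined (FALSE when
#'   the gene or index is constant).
#' @export
correlate_expr_index <- function(expr, indices, variant = c("significant", "all")) {
  variant <- match.arg(variant)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "log2") stop("correlate_expr_index expects log2 expression")
  cols <- if (variant == "significant") c(HyperZ = "HyperZ_sig", HypoZ = "HypoZ_sig")
          else c(HyperZ = "HyperZ", HypoZ = "HypoZ")
  if (!all(cols %in% names(indices)))
    stop("index table lacks column(s): ",
         paste(setdiff(cols, names(indices)), collapse = ", "))
  samples <- intersect(colnames(expr$values), indices$sample_id)
  n <- length(samples)
  if (n < 4) stop("need >= 4 matched cancer samples")
  e <- expr$values[, samples, drop = FALSE]
  idx <- indices[match(samples, indices$sample_id), , drop = FALSE]
  out <- list()
  for (ix in names(cols)) {
    y <- idx[[cols[[ix]]]]
    sd_g <- apply(e, 1, stats::sd)
    if (stats::sd(y) == 0) {
      r <- rep(NA_real_, nrow(e))
    } else {
      r <- suppressWarnings(as.vector(stats::cor(t(e), y)))
      r[sd_g == 0] <- NA_real_
    }
    finite_r <- !is.na(r) & abs(r) < 1
    z <- fisher_z(r)
    p <- ifelse(finite_r, 2 * stats::pnorm(-abs(z) * sqrt(n - 3)),
                ifelse(is.na(r), NA_real_, 0))
    out[[ix]] <- data.frame(gene = rownames(e), cohort = expr$cohort_id,
                            index = ix, r = r, z = z, p = p, n = n,
                            defined = finite_r, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-cohort consistency of expression-index correlations
#'
#' Counts cohorts with significant positive/negative correlation per gene and
#' index; a consistent call requires at least \code{m} cohorts with the same
#' sign.
#'
#' @param records row-bound \code{\link{correlate_expr_index}} outputs.
#' @param alpha nominal level (default 0.05).
#' @param m consistency threshold (default 6 of 10).
#' @return data.frame: gene, index, n_pos, n_neg, call
#'   (\code{positive}/\code{negative}/\code{none}).
#' @export
correlation_consistency <- function(records, alpha = 0.05, m = 6) {
  sig <- !is.na(records$p) & records$p < alpha
  key <- interaction(records$gene, records$index, drop = FALSE, sep = "\r")
  pos <- tapply(sig & records$r > 0, key, sum)
  neg <- tapply(sig & records$r < 0, key, sum)
  parts <- do.call(rbind, strsplit(names(pos), "\r", fixed = TRUE))
  call <- ifelse(pos >= m, "positive", ifelse(neg >= m, "negative", "none"))
  data.frame(gene = parts[, 1], index = parts[, 2],
             n_pos = as.integer(pos), n_neg = as.integer(neg),
             call = unname(call), stringsAsFactors = FALSE, row.names = NULL)
}

#' Average per-cohort null probabilities for correlation events
#'
#' Fractions of all genes with significant positive/negative correlation with
#' each index per cohort, averaged across cohorts (p_uu, p_du, p_ud, p_dd).
#'
#' @param records row-bound \code{\link{correlate_expr_index}} outputs over
#'   all genes.
#' @param alpha nominal level.
#' @return list with \code{p_uu}, \code{p_du}, \code{p_ud}, \code{p_dd}.
#' @export
cor_null_probs <- function(records, alpha = 0.05) {
  sig <- !is.na(records$p) & records$p < alpha
  f <- function(ixname, positive) {
    sel <- records$index == ixname
    ev <- sig[sel] & (if (positive) records$r[sel] > 0 else records$r[sel] < 0)
    mean(tapply(ev, records$cohort[sel], mean))
  }
  list(p_uu = f("HyperZ", TRUE), p_du = f("HyperZ", FALSE),
       p_ud = f("HypoZ", TRUE), p_dd = f("HypoZ", FALSE))
}

#' Expression-expression meta-correlation network
#'
#' For each pair of the selected genes, the per-cohort Pearson correlation
#' over cancer samples is Fisher-transformed and the cohort Z statistics are
#' combined by Stouffer's method with weights sqrt(n - 3). An edge is retained
#' if the combined two-sided P survives Bonferroni correction over pairs and
#' the per-cohort correlation sign agrees in more than half the contributing
#' cohorts; the edge sign is the sign of the combined Z.
#'
#' @param expr_list list of log2-scale \code{ExpressionMatrix}, one per cohort.
#' @param sheets list of matching sample sheets (cancer samples are used).
#' @param genes character vector of gene symbols.
#' @param alpha family-wise level before Bonferroni (default 0.05).
#' @return data.frame: gene_a, gene_b, z_combined, p, sign, n_cohorts,
#'   n_agreeing, edge (logical).
#' @export
expr_expr_meta_network <- function(expr_list, sheets, genes, alpha = 0.05) {
  stopifnot(length(expr_list) >= 1, length(expr_list) == length(sheets))
  pairs <- utils::combn(genes, 2)
  n_pairs <- ncol(pairs)
  per <- lapply(seq_along(expr_list), function(i) {
    e <- expr_list[[i]]
    if (e$scale != "log2") stop("expression must be log2 scale")
    sh <- validate_sample_sheet(sheets[[i]])
    canc <- sh$sample_id[sh$status == "cancer"]
    canc <- intersect(colnames(e$values), canc)
    g <- intersect(genes, rownames(e$values))
    list(vals = e$values[g, canc, drop = FALSE], n = length(canc))
  })
  rows <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    zs <- ns <- numeric(0)
    for (pc in per) {
      if (!all(c(a, b) %in% rownames(pc$vals)) || pc$n < 4) next
      r <- suppressWarnings(stats::cor(pc$vals[a, ], pc$vals[b, ]))
      if (is.na(r) || abs(r) >= 1) next
      zs <- c(zs, fisher_z(r))
      ns <- c(ns, pc$n)
    }
    if (!length(zs)) {
      rows[[j]] <- data.frame(gene_a = a, gene_b = b, z_combined = NA_real_,
                              p = NA_real_, sign = 0L, n_cohorts = 0L,
                              n_agreeing = 0L, stringsAsFactors = FALSE)
      next
    }
    w <- sqrt(ns - 3)
    z_comb <- sum(w * (zs * sqrt(ns - 3))) / sqrt(sum(w^2))
    p <- 2 * stats::pnorm(-abs(z_comb))
    sgn <- sign(z_comb)
    agree <- sum(sign(zs) == sgn)
    rows[[j]] <- data.frame(gene_a = a, gene_b = b, z_combined = z_comb,
                            p = p, sign = as.integer(sgn),
                            n_cohorts = length(zs), n_agreeing = agree,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$edge <- !is.na(out$p) & out$p < alpha / n_pairs &
    out$n_agreeing > out$n_cohorts / 2
  rownames(out) <- NULL
  out
}
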