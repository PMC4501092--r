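#' Regional clustering parameters
#'
#' @param max_cluster_width maximum cluster span in bp (default 1500).
#' @param max_gap maximum gap between neighboring probes in bp (default 500).
#' @return a \code{cluster_params} list.
#' @export
cluster_params <- function(max_cluster_width = 1500, max_gap = 500) {
  stopifnot(max_cluster_width > 0, max_gap > 0)
  structure(list(max_cluster_width = max_cluster_width, max_gap = max_gap),
            class = "cluster_params")
}

#' Group probes into regional clusters
#'
#' Within each (chromosome, region class) stratum, probes sorted by position
#' are grouped greedily left to right: a probe joins the current cluster iff
#' its gap to the previous probe is at most \code{max_gap} and the resulting
#' span (max - min position) stays at most \code{max_cluster_width};
#' otherwise a new cluster starts. Clusters never mix chromosomes or region
#' classes. This reproduces bounded-width cluster construction as used for
#' 450k regional summarization.
#'
#' @param ann probe annotation data.frame (see
#'   \code{\link{read_probe_annotation}}).
#' @param params \code{\link{cluster_params}}.
#' @return object of class \code{RegionalClusterSet}: list with
#'   \code{clusters} (data.frame: cluster_id, chromosome, region_class,
#'   promoter_cgi, promoter_gene, n_probes, start, end, span) and
#'   \code{members} (named list of position-sorted probe ids per cluster).
#' @export
cluster_probes <- function(ann, params = cluster_params()) {
  ann <- validate_probe_annotation(ann)
  strata <- split(ann, list(ann$chromosome, ann$region_class), drop = TRUE)
  members <- list()
  rows <- list()
  for (st in strata) {
    st <- st[order(st$position), , drop = FALSE]
    pos <- st$position
    grp <- integer(length(pos))
    cur <- 1L
    start_pos <- pos[1]
    grp[1] <- cur
    for (i in seq_along(pos)[-1]) {
      if (pos[i] - pos[i - 1] <= params$max_gap &&
          pos[i] - start_pos <= params$max_cluster_width) {
        grp[i] <- cur
      } else {
        cur <- cur + 1L
        start_pos <- pos[i]
        grp[i] <- cur
      }
    }
    for (g in seq_len(cur)) {
      sel <- st[grp == g, , drop = FALSE]
      cid <- sprintf("%s:%s:%d", sel$chromosome[1], sel$region_class[1],
                     sel$position[1])
      members[[cid]] <- sel$probe_id
      pg <- unique(sel$promoter_gene[!is.na(sel$promoter_gene)])
      rows[[cid]] <- data.frame(
        cluster_id = cid, chromosome = sel$chromosome[1],
        region_class = sel$region_class[1],
        promoter_cgi = all(sel$promoter_cgi),
        promoter_gene = if (length(pg) == 1) pg else NA_character_,
        n_probes = nrow(sel),
        start = min(sel$position), end = max(sel$position),
        span = max(sel$position) - min(sel$position),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, members = members),
            class = "RegionalClusterSet")
}

#' @export
print.RegionalClusterSet <- function(x, ...) {
  cat(sprintf("RegionalClusterSet: %d clusters (%s)\n", nrow(x$clusters),
              paste(sprintf("%s=%d", names(table(x$clusters$region_class)),
                            table(x$clusters$region_class)), collapse = ", ")))
  invisible(x)
}

#' Average betas over regional clusters
#'
#' The methylation level of a cluster in a sample is the mean beta of its
#' member probes.
#'
#' @param meth complete (imputed) \code{\link{methylation_matrix}}.
#' @param clusters \code{RegionalClusterSet}.
#' @return numeric matrix, clusters x samples.
#' @export
summarize_regions <- function(meth, clusters) {
  stopifnot(inherits(meth, "MethylationMatrix"),
            inherits(clusters, "RegionalClusterSet"))
  b <- meth$betas
  if (anyNA(b)) stop("methylation matrix must be complete (run filter_and_impute)")
  miss <- setdiff(unlist(clusters$members, use.names = FALSE), rownames(b))
  if (length(miss))
    stop("cluster member probe(s) absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- t(vapply(clusters$members, function(p)
    colMeans(b[p, , drop = FALSE]), numeric(ncol(b))))
  rownames(out) <- names(clusters$members)
  out
}

#' Z scores of cancer-sample region methylation against the normal reference
#'
#' For each cluster r the reference mean and sample standard deviation (n-1
#' denominator) are computed over the normal samples; each cancer sample's
#' region beta is then standardized: Z_rs = (beta_rs - mu_r) / sigma_r.
#' Clusters with zero normal-sample variance are excluded and reported.
#'
#' @param region_betas clusters x samples matrix from
#'   \code{\link{summarize_regions}}.
#' @param sheet sample sheet covering the matrix columns.
#' @return list with \code{reference} (data.frame cluster_id, mu, sd,
#'   n_normals), \code{z} (clusters x cancer samples), and \code{excluded}
#'   (ids of zero-variance clusters).
#' @export
compute_zscores <- function(region_betas, sheet) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(region_betas), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all matrix columns")
  norm_cols <- sheet$status == "normal"
  canc_cols <- sheet$status == "cancer"
  if (sum(norm_cols) < 2) stop("need >= 2 normal samples for the reference")
  bn <- region_betas[, norm_cols, drop = FALSE]
  mu <- rowMeans(bn)
  sdv <- apply(bn, 1, stats::sd)
  excluded <- rownames(region_betas)[sdv == 0]
  ok <- sdv > 0
  z <- (region_betas[ok, canc_cols, drop = FALSE] - mu[ok]) / sdv[ok]
  list(reference = data.frame(cluster_id = rownames(region_betas),
                              mu = mu, sd = sdv, n_normals = sum(norm_cols),
                              stringsAsFactors = FALSE, row.names = NULL),
       z = z, excluded = excluded)
}

#' HyperZ and HypoZ epigenetic instability indices
#'
#' HyperZ_s is the mean over promoter-CGI clusters of Z_rs * H(Z_rs), with
#' H(z) = 1 if z > 0 and 0 otherwise, so only hypermethylated deviations from
#' the (normally unmethylated) promoter-CGI reference contribute. HypoZ_s is
#' the mean over open-sea clusters of |Z_rs| * H(-Z_rs), capturing
#' hypomethylation from the (normally methylated) open-sea reference. The
#' \code{"significant"} variant restricts both the summation and its
#' denominator, per sample, to clusters whose Z passes the one-sided P < alpha
#' normal tail in the direction of interest (|Z| > 1.6449 at alpha = 0.05);
#' samples with no significant cluster get index 0.
#'
#' @param z result of \code{\link{compute_zscores}}.
#' @param clusters \code{RegionalClusterSet} used for the region betas.
#' @param variant \code{"all"} or \code{"significant"}.
#' @param alpha one-sided significance level for the significant variant.
#' @return data.frame: sample_id, HyperZ, HypoZ, n_hyper, n_hypo (cluster
#'   counts entering each average; per-sample for the significant variant).
#' @export
compute_indices <- function(z, clusters, variant = c("all", "significant"),
                            alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(clusters, "RegionalClusterSet"))
  zm <- z$z
  info <- clusters$clusters[match(rownames(zm), clusters$clusters$cluster_id), ]
  hyper_rows <- which(info$promoter_cgi)
  hypo_rows <- which(info$region_class == "opensea")
  if (!length(hyper_rows)) stop("no promoter-CGI clusters available for HyperZ")
  if (!length(hypo_rows)) stop("no open-sea clusters available for HypoZ")
  crit <- stats::qnorm(1 - alpha)
  idx_one <- function(rows, sign) {
    zz <- zm[rows, , drop = FALSE] * sign      # deviation in direction of interest
    contrib <- zz * (zz > 0)
    if (variant == "all") {
      list(v = colSums(contrib) / length(rows),
           n = rep(length(rows), ncol(zm)))
    } else {
      sig <- zz > crit
      n <- colSums(sig)
      v <- colSums(contrib * sig)
      v <- ifelse(n > 0, v / n, 0)
      list(v = v, n = n)
    }
  }
  hyper <- idx_one(hyper_rows, 1)
  hypo <- idx_one(hypo_rows, -1)
  data.frame(sample_id = colnames(zm), HyperZ = unname(hyper$v),
             HypoZ = unname(hypo$v), n_hyper = unname(hyper$n),
             n_hypo = unname(hypo$n), stringsAsFactors = FALSE)
}

#' Both index variants in one table
#'
#' Convenience wrapper running the whole region-summarization / z-scoring /
#' index chain for one cohort, returning the all-regions and
#' significant-regions variants side by side.
#'
#' @param meth complete \code{MethylationMatrix}.
#' @param clusters \code{RegionalClusterSet}.
#' @param sheet sample sheet.
#' @param alpha one-sided level for the significant variant.
#' @return data.frame: sample_id, HyperZ, HypoZ, HyperZ_sig, HypoZ_sig.
#' @export
instability_indices <- function(meth, clusters, sheet, alpha = 0.05) {
  rb <- summarize_regions(meth, clusters)
  z <- compute_zscores(rb, sheet)
  a <- compute_indices(z, clusters, "all")
  s <- compute_indices(z, clusters, "significant", alpha)
  data.frame(sample_id = a$sample_id, HyperZ = a$HyperZ, HypoZ = a$HypoZ,
             HyperZ_sig = s$HyperZ, HypoZ_sig = s$HypoZ,
             stringsAsFactors = FALSE)
}

#' Association between HyperZ and HypoZ across cancer samples
#'
#' @param table index table with columns \code{HyperZ} and \code{HypoZ} (or
#'   the \code{_sig} variants via \code{cols}).
#' @param cols length-2 character vector naming the two index columns.
#' @return list with \code{rho} (Spearman), \code{p} and \code{r_squared}
#'   (linear model); \code{rho}/\code{p} are NA when an index is constant.
#' @export
index_association <- function(table, cols = c("HyperZ", "HypoZ")) {
  x <- table[[cols[1]]]
  y <- table[[cols[2]]]
  if (length(x) < 3) stop("need >= 3 cancer samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, r_squared = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  fit <- suppressWarnings(summary(stats::lm(y ~ x)))  # perfect fits are legal
  list(rho = unname(ct$estimate), p = ct$p.value, r_squared = fit$r.squared)
}
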