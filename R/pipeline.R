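#' Pipeline configuration
#'
#' Bundles either a simulation configuration or pre-loaded cohort data with
#' every threshold of the analysis. Defaults are the study conditions: nominal
#' alpha 0.05 everywhere, differential-expression consistency in >= 8 of 10
#' cohorts, correlation and causal consistency in >= 6 of 10, regional
#' clustering bounded at 1500 bp width / 500 bp gap, and the
#' significant-regions index variant for the correlation and causal stages.
#'
#' @param sim \code{\link{sim_config}} describing data to generate, or NULL
#'   when \code{data} is supplied.
#' @param data pre-built dataset shaped like \code{\link{simulate_pan_cancer}}
#'   output (fields \code{cohorts}, \code{annotation}, \code{ee_genes}).
#' @param alpha nominal per-cohort significance level.
#' @param m_de differential-expression consistency threshold.
#' @param m_cor correlation consistency threshold.
#' @param m_causal causal consensus threshold.
#' @param clusters \code{\link{cluster_params}}.
#' @param index_variant variant used for correlation/causal stages.
#' @param max_na_fraction,k_impute methylation preprocessing parameters.
#' @param do_qc run SVD quality control per cohort.
#' @param outdir optional directory; when set, every intermediate table is
#'   written as TSV.
#' @param seed RNG seed (overrides \code{sim$seed} when \code{sim} is given).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_config(), data = NULL, alpha = 0.05,
                            m_de = 8, m_cor = 6, m_causal = 6,
                            clusters = cluster_params(),
                            index_variant = c("significant", "all"),
                            max_na_fraction = 0.70, k_impute = 10,
                            do_qc = TRUE, outdir = NULL, seed = NULL) {
  index_variant <- match.arg(index_variant)
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, data = data, alpha = alpha, m_de = m_de,
                 m_cor = m_cor, m_causal = m_causal, clusters = clusters,
                 index_variant = index_variant,
                 max_na_fraction = max_na_fraction, k_impute = k_impute,
                 do_qc = do_qc, outdir = outdir,
                 seed = if (!is.null(seed)) as.integer(seed)
                        else if (!is.null(sim)) sim$seed else NA_integer_),
            class = "pipeline_config")
}

#' Run the full pan-cancer analysis
#'
#' Stage order: (1) obtain or simulate matched cohorts; (2) per cohort:
#' expression log2 preprocessing, methylation NA filtering + KNN imputation,
#' optional SVD QC; (3) regional clustering (shared manifest) and HyperZ/HypoZ
#' index computation (both variants); (4) differential-expression
#' meta-analysis with the binomial consistency null; (5) expression-index
#' correlation meta-analysis with its binomial null; (6) candidate regulators
#' = genes passing both consistency filters with matching directionality
#' (overexpressed genes must correlate positively, underexpressed negatively);
#' (7) single-gene and full-model partial-correlation causal tests on the
#' candidates and the consensus network (built from the full model); (8)
#' locus-level correlations for consensus genes and cross-cohort rank
#' consistency against the first cohort. Reruns with the same config and seed
#' are bit-identical.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return a \code{run_report} list; see the fields written by each stage.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("data", {
    if (!is.null(config$data)) config$data else simulate_pan_cancer(config$sim)
  })
  T_cohorts <- length(ds$cohorts)
  m_de <- min(config$m_de, T_cohorts)
  m_cor <- min(config$m_cor, T_cohorts)
  m_causal <- min(config$m_causal, T_cohorts)
  if (T_cohorts < config$m_de || T_cohorts < config$m_cor)
    warning("fewer cohorts (", T_cohorts, ") than consistency thresholds; ",
            "thresholds clamped to the cohort count")
  ee_genes <- ds$ee_genes

  clusters <- stage("clustering", cluster_probes(ds$annotation, config$clusters))

  per <- vector("list", T_cohorts)
  names(per) <- names(ds$cohorts)
  log_counts <- list()
  for (cn in names(ds$cohorts)) {
    co <- ds$cohorts[[cn]]
    aligned <- stage("align", align_cohort(co$expr, co$meth, co$sheet))
    expr <- stage("preprocess_expression", {
      if (aligned$expr$scale == "raw") preprocess_expression(aligned$expr)
      else aligned$expr
    })
    meth <- stage("filter_and_impute",
                  filter_and_impute(aligned$meth, config$max_na_fraction,
                                    config$k_impute))
    qc <- NULL
    if (config$do_qc)
      qc <- stage("svd_qc", svd_qc(expr$values,
                                   aligned$sheet[, "status", drop = FALSE]))
    rb <- stage("summarize_regions", summarize_regions(meth, clusters))
    zres <- stage("compute_zscores", compute_zscores(rb, aligned$sheet))
    idx_all <- stage("indices", {
      a <- compute_indices(zres, clusters, "all")
      s <- compute_indices(zres, clusters, "significant", config$alpha)
      data.frame(sample_id = a$sample_id, HyperZ = a$HyperZ, HypoZ = a$HypoZ,
                 HyperZ_sig = s$HyperZ, HypoZ_sig = s$HypoZ,
                 stringsAsFactors = FALSE)
    })
    assoc <- stage("index_association", index_association(idx_all))
    per[[cn]] <- list(expr = expr, meth = meth, sheet = aligned$sheet,
                      region_betas = rb, z = zres, indices = idx_all,
                      index_association = assoc, qc = qc)
    log_counts[[cn]] <- c(samples = nrow(aligned$sheet),
                          dropped_samples = sum(aligned$dropped),
                          dropped_probes = attr(meth, "n_dropped"),
                          excluded_clusters = length(zres$excluded))
  }

  ## ---- differential-expression meta-analysis ----------------------------
  de_records <- stage("moderated_t", do.call(rbind, lapply(per, function(p)
    moderated_t(p$expr, p$sheet))))
  de_cons_all <- consistency_count(de_records, config$alpha, m_de)
  de_cons <- de_cons_all[de_cons_all$gene %in% ee_genes, , drop = FALSE]
  de_null <- de_null_probs(de_records, config$alpha)
  de_tail_up <- binomial_tail(T_cohorts, m_de, de_null$p_u)
  de_tail_dn <- binomial_tail(T_cohorts, m_de, de_null$p_d)
  n_up <- sum(de_cons$call == "up")
  n_dn <- sum(de_cons$call == "down")
  pool <- length(ee_genes)
  de_meta <- list(
    null = de_null, tail_up = de_tail_up, tail_down = de_tail_dn,
    expected_up = expected_random_count(pool, de_tail_up),
    expected_down = expected_random_count(pool, de_tail_dn),
    observed_up = n_up, observed_down = n_dn,
    p_up = meta_significance(n_up, pool, de_tail_up),
    p_down = meta_significance(n_dn, pool, de_tail_dn))

  ## ---- correlation meta-analysis ----------------------------------------
  cor_records <- stage("correlate_expr_index", do.call(rbind, lapply(per,
    function(p) {
      canc <- p$sheet$sample_id[p$sheet$status == "cancer"]
      idx <- p$indices[p$indices$sample_id %in% canc, , drop = FALSE]
      correlate_expr_index(p$expr, idx, config$index_variant)
    })))
  cor_cons_all <- correlation_consistency(cor_records, config$alpha, m_cor)
  cor_cons <- cor_cons_all[cor_cons_all$gene %in% ee_genes, , drop = FALSE]
  cor_null <- cor_null_probs(cor_records, config$alpha)
  cor_meta <- list(null = cor_null,
                   tails = list(
                     uu = binomial_tail(T_cohorts, m_cor, cor_null$p_uu),
                     du = binomial_tail(T_cohorts, m_cor, cor_null$p_du),
                     ud = binomial_tail(T_cohorts, m_cor, cor_null$p_ud),
                     dd = binomial_tail(T_cohorts, m_cor, cor_null$p_dd)))

  ## ---- candidate regulators: both filters + matching direction ----------
  de_call <- stats::setNames(de_cons$call, de_cons$gene)
  cand_rows <- cor_cons[cor_cons$call != "none", , drop = FALSE]
  keep <- vapply(seq_len(nrow(cand_rows)), function(i) {
    g <- cand_rows$gene[i]
    dc <- de_call[g]
    !is.na(dc) && ((dc == "up" && cand_rows$call[i] == "positive") ||
                     (dc == "down" && cand_rows$call[i] == "negative"))
  }, TRUE)
  candidates <- cand_rows[keep, , drop = FALSE]
  cand_genes <- unique(candidates$gene)

  ## ---- expression-expression meta network over candidates ---------------
  meta_net <- NULL
  if (length(cand_genes) >= 2)
    meta_net <- stage("expr_expr_meta_network",
                      expr_expr_meta_network(lapply(per, `[[`, "expr"),
                                             lapply(per, `[[`, "sheet"),
                                             cand_genes, config$alpha))

  ## ---- causal stage ------------------------------------------------------
  causal_single <- causal_full <- NULL
  consensus <- data.frame(gene = character(0), index = character(0),
                          sign = integer(0), n_support = integer(0))
  if (length(cand_genes) >= 1) {
    recs_single <- list()
    recs_full <- list()
    for (cn in names(per)) {
      p <- per[[cn]]
      canc <- p$sheet$sample_id[p$sheet$status == "cancer"]
      idx <- p$indices[p$indices$sample_id %in% canc, , drop = FALSE]
      pm <- promoter_methylation(p$region_betas, clusters, cand_genes)
      for (g in cand_genes) {
        pv <- if (g %in% rownames(pm)) pm[g, ] else NULL
        recs_single[[paste(cn, g)]] <-
          single_gene_causal_test(g, p$expr, pv, idx, config$index_variant,
                                  config$alpha)
      }
      recs_full[[cn]] <- stage("full_model_causal_test",
        full_model_causal_test(cand_genes, p$expr, pm, idx,
                               config$index_variant, config$alpha))
    }
    causal_single <- do.call(rbind, recs_single)
    causal_full <- do.call(rbind, recs_full)
    rownames(causal_single) <- rownames(causal_full) <- NULL
    consensus <- build_consensus(causal_full, config$alpha, m_causal)
  }

  ## ---- locus-level consistency for consensus genes -----------------------
  loci <- list()
  if (nrow(consensus)) {
    for (i in seq_len(nrow(consensus))) {
      g <- consensus$gene[i]
      restr <- if (consensus$index[i] == "HyperZ") "cgi" else "opensea"
      tabs <- lapply(per, function(p)
        locus_correlations(p$region_betas, p$expr, g, clusters, p$sheet, restr))
      dir <- if (consensus$sign[i] > 0) "descending" else "ascending"
      loci[[paste(g, consensus$index[i], sep = ":")]] <-
        stage("rank_consistency", rank_consistency(tabs, 1, dir))
    }
  }

  report <- list(
    config = config, n_cohorts = T_cohorts, pool = pool,
    clusters = clusters, counts = log_counts,
    cohorts = per,
    de_records = de_records, de_consistency = de_cons, de_meta = de_meta,
    cor_records = cor_records, cor_consistency = cor_cons,
    cor_meta = cor_meta,
    candidates = candidates, candidate_genes = cand_genes,
    meta_network = meta_net,
    causal_single = causal_single, causal_full = causal_full,
    consensus = consensus, loci = loci,
    truth = ds$truth)
  class(report) <- "run_report"
  if (!is.null(config$outdir)) .write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("methylZ run report\n")
  cat(sprintf("  cohorts: %d; EE pool: %d genes\n", x$n_cohorts, x$pool))
  cat(sprintf("  consistently deregulated EE genes: %d up, %d down (meta P: %.3g / %.3g)\n",
              x$de_meta$observed_up, x$de_meta$observed_down,
              x$de_meta$p_up, x$de_meta$p_down))
  cat(sprintf("  candidate regulators (DE + correlation, direction-matched): %s\n",
              if (length(x$candidate_genes)) paste(x$candidate_genes, collapse = ", ")
              else "none"))
  if (nrow(x$consensus)) {
    cat("  consensus network edges:\n")
    for (i in seq_len(nrow(x$consensus)))
      cat(sprintf("    %s %s HyperZ/HypoZ[%s] (n = %d cohorts)\n",
                  x$consensus$gene[i],
                  ifelse(x$consensus$sign[i] > 0, "--(+)-->", "--(-)-->"),
                  x$consensus$index[i], x$consensus$n_support[i]))
  } else cat("  consensus network: no edges\n")
  invisible(x)
}

.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  wt(report$clusters$clusters, "clusters.tsv")
  wt(report$de_records, "de_records.tsv")
  wt(report$de_consistency, "de_consistency.tsv")
  wt(report$cor_records, "cor_records.tsv")
  wt(report$cor_consistency, "cor_consistency.tsv")
  wt(report$candidates, "candidates.tsv")
  if (!is.null(report$causal_full)) {
    wt(report$causal_single, "causal_single.tsv")
    wt(report$causal_full, "causal_full.tsv")
  }
  wt(report$consensus, "consensus_edges.tsv")
  if (!is.null(report$meta_network)) wt(report$meta_network, "meta_network.tsv")
  for (nm in names(report$loci))
    wt(report$loci[[nm]]$report,
       paste0("rank_consistency_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv"))
  for (cn in names(report$cohorts))
    wt(report$cohorts[[cn]]$indices, paste0("indices_", cn, ".tsv"))
  invisible(outdir)
}
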