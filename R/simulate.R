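#' Driver specification for the synthetic generator
#'
#' Describes how one epigenetic-enzyme (EE) gene is wired to the latent
#' per-sample methylation-shift magnitudes. The three generative models mirror
#' the causal alternatives the partial-correlation stage is designed to
#' separate:
#' \itemize{
#'   \item \code{C_hyper}/\code{C_hypo}: direct driver - the gene's log2
#'     expression deviation scales with the sample's hyper- (resp. hypo-)
#'     methylation magnitude.
#'   \item \code{A_confounded}: the gene's own promoter lies in a
#'     hyper-affected region and its expression is a function of its own
#'     promoter methylation only, creating a spurious marginal association
#'     with the instability index.
#'   \item \code{B_correlated}: the gene's expression tracks a direct driver's
#'     expression, with no link of its own to the methylome.
#'   \item \code{null}: independent noise.
#' }
#'
#' @param gene gene symbol (must be among the simulated EE genes).
#' @param model one of \code{"C_hyper"}, \code{"C_hypo"}, \code{"A_confounded"},
#'   \code{"B_correlated"}, \code{"null"}.
#' @param direction \code{"up"} or \code{"down"}: sign of the expression
#'   deviation in cancer.
#' @param effect slope linking the gene's log2 expression deviation to the
#'   per-sample latent shift magnitude (unit half-normal scale).
#' @param frac_regions fraction of regions of the relevant class affected by
#'   the methylation process the driver is tied to.
#' @return a \code{driver_spec} list.
#' @export
driver_spec <- function(gene, model = c("C_hyper", "C_hypo", "A_confounded",
                                        "B_correlated", "null"),
                        direction = c("up", "down"), effect = 1,
                        frac_regions = 0.5) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  stopifnot(is.finite(effect), frac_regions > 0, frac_regions <= 1)
  structure(list(gene = gene, model = model, direction = direction,
                 effect = effect, frac_regions = frac_regions),
            class = "driver_spec")
}

#' Default planted drivers
#'
#' Two direct hypermethylation drivers (overexpressed), one direct
#' hypomethylation driver (underexpressed), one promoter-confounded gene and
#' one driver-correlated passenger.
#' @return list of \code{driver_spec}.
#' @export
default_drivers <- function() {
  list(driver_spec("UHRF1", "C_hyper", "up", 1.0),
       driver_spec("WHSC1", "C_hyper", "up", 1.0),
       driver_spec("CBX7",  "C_hypo",  "down", 1.0),
       driver_spec("EYA4",  "A_confounded", "down", 1.0),
       driver_spec("EZH2",  "B_correlated", "up", 0.8))
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' ten cohorts of 20 normals + 80 cancers, promoter-CGI regions unmethylated
#' (mean beta 0.10) and open-sea regions methylated (mean beta 0.80) in
#' normals, sample-specific hyper/hypo magnitudes drawn as independent unit
#' half-normals and converted to beta shifts with scale
#' \code{beta_shift_scale} and per-region weights in U(0.5, 1), giving a mean
#' cancer CGI beta shift of about 0.15 in affected regions.
#'
#' @param n_cohorts number of cohorts (cancer types).
#' @param n_normal,n_cancer samples per cohort.
#' @param n_genes total genes; the first \code{n_ee} are EE genes drawn from
#'   the bundled list.
#' @param n_ee number of EE genes.
#' @param n_cgi_regions,n_opensea_regions regions per class.
#' @param probes_per_region probes per region.
#' @param cgi_mean,opensea_mean normal-tissue baseline betas per class.
#' @param beta_noise_sd per-sample beta measurement noise sd.
#' @param expr_noise_sd log2 expression noise sd.
#' @param na_rate methylation missing-data rate.
#' @param beta_shift_scale converts a unit latent magnitude into a beta shift.
#' @param region_noise_shape Gamma shape (= rate, so the mean is 1) of the
#'   per-region, per-sample multiplicative shift noise that makes aberrant
#'   methylation locus-stochastic.
#' @param drivers list of \code{\link{driver_spec}}.
#' @param seed integer RNG seed, recorded in the output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_cohorts = 10, n_normal = 20, n_cancer = 80,
                       n_genes = 300, n_ee = 40,
                       n_cgi_regions = 200, n_opensea_regions = 200,
                       probes_per_region = 3,
                       cgi_mean = 0.10, opensea_mean = 0.80,
                       beta_noise_sd = 0.03, expr_noise_sd = 0.5,
                       na_rate = 0.01, beta_shift_scale = 0.25,
                       region_noise_shape = 2,
                       drivers = default_drivers(), seed = 1L) {
  cfg <- list(n_cohorts = n_cohorts, n_normal = n_normal, n_cancer = n_cancer,
              n_genes = n_genes, n_ee = n_ee,
              n_cgi_regions = n_cgi_regions,
              n_opensea_regions = n_opensea_regions,
              probes_per_region = probes_per_region,
              cgi_mean = cgi_mean, opensea_mean = opensea_mean,
              beta_noise_sd = beta_noise_sd, expr_noise_sd = expr_noise_sd,
              na_rate = na_rate, beta_shift_scale = beta_shift_scale,
              region_noise_shape = region_noise_shape,
              drivers = drivers, seed = as.integer(seed))
  counts <- c(n_cohorts, n_normal, n_cancer, n_genes, n_ee, n_cgi_regions,
              n_opensea_regions, probes_per_region)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cgi_mean <= 0 || cgi_mean >= 1 || opensea_mean <= 0 || opensea_mean >= 1)
    stop("baseline beta means must lie in (0,1)")
  if (length(drivers) > n_ee)
    stop("more drivers requested than EE genes available (",
         length(drivers), " > ", n_ee, ")")
  if (n_normal < 2 || n_cancer < 2)
    stop("each cohort needs >= 2 normals and >= 2 cancers")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-cohort matched expression/methylation study
#'
#' Generates, for each cohort, an RSEM-like raw expression matrix, a beta
#' matrix with missing values, and a sample sheet, plus one probe annotation
#' shared across cohorts (fixed array manifest) and the full planted ground
#' truth. Normals scatter around the class baselines; each cancer sample
#' carries independent latent hyper/hypo magnitudes that shift affected
#' promoter-CGI regions up and affected open-sea regions down; planted EE
#' genes realize the direct-driver, promoter-confounded and driver-correlated
#' generative models (see \code{\link{driver_spec}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohorts} (each: \code{expr}, \code{meth},
#'   \code{sheet}), \code{annotation}, \code{ee_genes}, and \code{truth}
#'   (latent magnitudes, gene models, region flags, config).
#' @export
simulate_pan_cancer <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  ee_all <- read_ee_genes()
  if (cfg$n_ee > length(ee_all))
    stop("n_ee exceeds the bundled EE gene list (", length(ee_all), ")")
  ee_genes <- ee_all[seq_len(cfg$n_ee)]
  drv_genes <- vapply(cfg$drivers, `[[`, "", "gene")
  if (!all(drv_genes %in% ee_genes))
    stop("driver gene(s) not among the simulated EE genes: ",
         paste(setdiff(drv_genes, ee_genes), collapse = ", "))
  bg <- sprintf("BG%03d", seq_len(cfg$n_genes - cfg$n_ee))
  genes <- c(ee_genes, bg)

  ## ---- shared probe manifest -------------------------------------------
  ppr <- cfg$probes_per_region
  n_reg <- c(cgi = cfg$n_cgi_regions, opensea = cfg$n_opensea_regions)
  region_class <- rep(c("cgi", "opensea"), times = n_reg)
  region_id <- sprintf("R_%s_%04d", region_class,
                       c(seq_len(n_reg["cgi"]), seq_len(n_reg["opensea"])))
  n_regions <- length(region_id)
  reg_of_probe <- rep(seq_len(n_regions), each = ppr)
  pos_in_reg <- rep(seq_len(ppr) - 1L, times = n_regions) * 100L
  reg_index_in_class <- c(seq_len(n_reg["cgi"]), seq_len(n_reg["opensea"]))
  position <- (reg_index_in_class[reg_of_probe] - 1L) * 10000L + 1L + pos_in_reg
  chromosome <- ifelse(region_class[reg_of_probe] == "cgi", "chrCGI", "chrSEA")
  promoter_gene_region <- rep(NA_character_, n_regions)
  promoter_gene_region[seq_len(min(cfg$n_ee, n_reg["cgi"]))] <-
    ee_genes[seq_len(min(cfg$n_ee, n_reg["cgi"]))]
  annotation <- data.frame(
    probe_id = sprintf("cg%06d", seq_along(reg_of_probe)),
    chromosome = chromosome,
    position = position,
    region_class = region_class[reg_of_probe],
    promoter_gene = promoter_gene_region[reg_of_probe],
    promoter_cgi = region_class[reg_of_probe] == "cgi",
    stringsAsFactors = FALSE)
  validate_probe_annotation(annotation)

  ## ---- region ground truth ---------------------------------------------
  weight <- stats::runif(n_regions, 0.5, 1)
  frac_hyper <- max(c(0, vapply(cfg$drivers, function(d)
    if (d$model %in% c("C_hyper", "A_confounded")) d$frac_regions else 0, 0)))
  frac_hypo <- max(c(0, vapply(cfg$drivers, function(d)
    if (d$model == "C_hypo") d$frac_regions else 0, 0)))
  is_cgi_reg <- region_class == "cgi"
  affected_hyper <- rep(FALSE, n_regions)
  affected_hypo <- rep(FALSE, n_regions)
  # promoter regions of non-confounded EE genes stay unaffected: their
  # expression deviations are transcriptionally driven, not methylation-driven
  ee_promoter_reg <- which(!is.na(promoter_gene_region))
  a_genes <- drv_genes[vapply(cfg$drivers, `[[`, "", "model") == "A_confounded"]
  a_promoter_reg <- ee_promoter_reg[promoter_gene_region[ee_promoter_reg] %in% a_genes]
  eligible_hyper <- setdiff(which(is_cgi_reg), ee_promoter_reg)
  n_hyper <- round(frac_hyper * sum(is_cgi_reg))
  if (n_hyper > 0)
    affected_hyper[sample(eligible_hyper, min(n_hyper, length(eligible_hyper)))] <- TRUE
  affected_hyper[a_promoter_reg] <- TRUE
  eligible_hypo <- which(!is_cgi_reg)
  n_hypo <- round(frac_hypo * sum(!is_cgi_reg))
  if (n_hypo > 0)
    affected_hypo[sample(eligible_hypo, min(n_hypo, length(eligible_hypo)))] <- TRUE

  probe_base <- ifelse(annotation$region_class == "cgi", cfg$cgi_mean,
                       cfg$opensea_mean) + stats::rnorm(nrow(annotation), 0, 0.01)
  probe_base <- pmin(pmax(probe_base, 0.02), 0.98)
  gene_base <- stats::runif(cfg$n_genes, 3, 8)
  names(gene_base) <- genes

  ## per-probe shift multipliers (0 where the probe's region is unaffected)
  shift_hyper <- cfg$beta_shift_scale * weight[reg_of_probe] *
    affected_hyper[reg_of_probe]
  shift_hypo <- cfg$beta_shift_scale * weight[reg_of_probe] *
    affected_hypo[reg_of_probe]

  model_of <- stats::setNames(rep("null", cfg$n_genes), genes)
  dir_of <- stats::setNames(rep("up", cfg$n_genes), genes)
  for (d in cfg$drivers) {
    model_of[d$gene] <- d$model
    dir_of[d$gene] <- d$direction
  }
  first_driver <- {
    ch <- drv_genes[vapply(cfg$drivers, `[[`, "", "model") == "C_hyper"]
    if (length(ch)) ch[1] else {
      cl <- drv_genes[vapply(cfg$drivers, `[[`, "", "model") == "C_hypo"]
      if (length(cl)) cl[1] else NA_character_
    }
  }
  if (any(model_of == "B_correlated") && is.na(first_driver))
    stop("B_correlated drivers require at least one model-C driver")

  ## ---- per-cohort data --------------------------------------------------
  cohorts <- vector("list", cfg$n_cohorts)
  names(cohorts) <- sprintf("C%02d", seq_len(cfg$n_cohorts))
  latent <- vector("list", cfg$n_cohorts)
  n_probe <- nrow(annotation)
  for (ci in seq_len(cfg$n_cohorts)) {
    cid <- names(cohorts)[ci]
    s_norm <- sprintf("%s_N%03d", cid, seq_len(cfg$n_normal))
    s_canc <- sprintf("%s_T%03d", cid, seq_len(cfg$n_cancer))
    samples <- c(s_norm, s_canc)
    n_s <- length(samples)
    ## Each direct driver contributes an independent latent component; the
    ## sample's effective magnitude is the mean of its components, so two
    ## drivers of the same process remain statistically separable while the
    ## overall beta-shift calibration is unchanged.
    hyper_drv <- drv_genes[vapply(cfg$drivers, `[[`, "", "model") == "C_hyper"]
    hypo_drv <- drv_genes[vapply(cfg$drivers, `[[`, "", "model") == "C_hypo"]
    H <- matrix(abs(stats::rnorm(cfg$n_cancer * max(1L, length(hyper_drv)))),
                cfg$n_cancer)
    colnames(H) <- if (length(hyper_drv)) hyper_drv else "latent"
    L <- matrix(abs(stats::rnorm(cfg$n_cancer * max(1L, length(hypo_drv)))),
                cfg$n_cancer)
    colnames(L) <- if (length(hypo_drv)) hypo_drv else "latent"
    h <- rowMeans(H)
    l <- rowMeans(L)

    betas <- matrix(probe_base, n_probe, n_s) +
      matrix(stats::rnorm(n_probe * n_s, 0, cfg$beta_noise_sd), n_probe, n_s)
    canc_cols <- cfg$n_normal + seq_len(cfg$n_cancer)
    ## Aberrant methylation is locus-stochastic: each region's realized shift
    ## is the sample magnitude times an independent Gamma(mean 1) factor, so a
    ## single region is a noisy readout of the global process while the index
    ## (an average over many regions) remains a clean one.
    Uh <- matrix(stats::rgamma(n_regions * cfg$n_cancer,
                               shape = cfg$region_noise_shape,
                               rate = cfg$region_noise_shape),
                 n_regions, cfg$n_cancer)
    Ul <- matrix(stats::rgamma(n_regions * cfg$n_cancer,
                               shape = cfg$region_noise_shape,
                               rate = cfg$region_noise_shape),
                 n_regions, cfg$n_cancer)
    betas[, canc_cols] <- betas[, canc_cols] +
      outer(shift_hyper, h) * Uh[reg_of_probe, , drop = FALSE] -
      outer(shift_hypo, l) * Ul[reg_of_probe, , drop = FALSE]
    betas <- pmin(pmax(betas, 0), 1)
    dimnames(betas) <- list(annotation$probe_id, samples)

    expr <- matrix(gene_base, cfg$n_genes, n_s) +
      matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$expr_noise_sd),
             cfg$n_genes, n_s)
    dimnames(expr) <- list(genes, samples)
    for (d in cfg$drivers) {
      sgn <- if (d$direction == "up") 1 else -1
      g <- d$gene
      if (d$model == "C_hyper") {
        expr[g, canc_cols] <- expr[g, canc_cols] + sgn * d$effect * H[, g]
      } else if (d$model == "C_hypo") {
        expr[g, canc_cols] <- expr[g, canc_cols] + sgn * d$effect * L[, g]
      } else if (d$model == "A_confounded") {
        preg <- which(promoter_gene_region == g)
        probes <- which(reg_of_probe == preg)
        prom_beta <- colMeans(betas[probes, , drop = FALSE])
        # expression is a function of the gene's own promoter methylation only
        expr[g, ] <- gene_base[g] +
          sgn * 5 * d$effect * (prom_beta - cfg$cgi_mean) +
          stats::rnorm(n_s, 0, cfg$expr_noise_sd)
      }
    }
    for (d in cfg$drivers) {
      if (d$model == "B_correlated") {
        sgn <- if (d$direction == "up") 1 else -1
        expr[d$gene, ] <- gene_base[d$gene] +
          sgn * d$effect * (expr[first_driver, ] - gene_base[first_driver]) +
          stats::rnorm(n_s, 0, cfg$expr_noise_sd)
      }
    }

    if (cfg$na_rate > 0) {
      nas <- stats::runif(length(betas)) < cfg$na_rate
      betas[nas] <- NA_real_
    }

    sheet <- data.frame(
      sample_id = samples,
      status = rep(c("normal", "cancer"), c(cfg$n_normal, cfg$n_cancer)),
      cohort_id = cid, group = NA_character_, stringsAsFactors = FALSE)

    cohorts[[ci]] <- list(
      expr = expression_matrix(2^expr, cohort_id = cid, scale = "raw"),
      meth = methylation_matrix(betas, cohort_id = cid),
      sheet = sheet)
    latent[[ci]] <- data.frame(cohort_id = cid, sample_id = s_canc,
                               h = h, l = l, stringsAsFactors = FALSE)
  }

  truth <- list(
    latent = do.call(rbind, latent),
    genes = data.frame(gene = genes, model = unname(model_of),
                       direction = unname(dir_of), stringsAsFactors = FALSE),
    regions = data.frame(region_id = region_id, region_class = region_class,
                         promoter_gene = promoter_gene_region,
                         affected_hyper = affected_hyper,
                         affected_hypo = affected_hypo,
                         weight = weight, stringsAsFactors = FALSE),
    config = cfg)
  list(cohorts = cohorts, annotation = annotation, ee_genes = ee_genes,
       truth = truth)
}

#' Tiny hand-computable single-cohort fixture
#'
#' Four normals, two cancers, two singleton promoter-CGI regions and one gene.
#' Region betas in the normals are \{0.10, 0.12, 0.08, 0.10\} (mean 0.10,
#' sample sd 0.016330). Cancer sample T1 has beta 0.30 in region 1 (z =
#' 12.247) and mean - 1 sd in region 2 (z = -1), so its two-cluster HyperZ is
#' 12.247/2 = 6.1237; cancer sample T2 sits exactly at the normal means, so
#' its HyperZ is 0. Expected values are attached as \code{attr(, "expected")}.
#'
#' @return list with \code{meth}, \code{expr}, \code{sheet},
#'   \code{annotation}; deterministic and constant across calls.
#' @export
worked_fixture <- function() {
  normals <- c(0.10, 0.12, 0.08, 0.10)
  sd_n <- stats::sd(normals)                       # 0.01632993
  samples <- c(paste0("N", 1:4), "T1", "T2")
  betas <- rbind(
    cg1 = c(normals, 0.30, 0.10),
    cg2 = c(normals, 0.10 - sd_n, 0.10))
  colnames(betas) <- samples
  annotation <- data.frame(
    probe_id = c("cg1", "cg2"), chromosome = "chrF",
    position = c(100L, 5000L), region_class = "cgi",
    promoter_gene = c("UHRF1", NA), promoter_cgi = TRUE,
    stringsAsFactors = FALSE)
  expr <- matrix(2^c(5.0, 5.1, 4.9, 5.0, 6.2, 5.1), 1,
                 dimnames = list("UHRF1", samples))
  sheet <- data.frame(sample_id = samples,
                      status = rep(c("normal", "cancer"), c(4, 2)),
                      cohort_id = "FIX", group = NA_character_,
                      stringsAsFactors = FALSE)
  out <- list(meth = methylation_matrix(betas, "FIX"),
              expr = expression_matrix(expr, "FIX", "raw"),
              sheet = sheet,
              annotation = validate_probe_annotation(annotation))
  attr(out, "expected") <- list(
    mu = 0.10, sd = sd_n,
    z_T1 = c(0.20 / sd_n, -1), z_T2 = c(0, 0),
    hyperz_T1 = (0.20 / sd_n) / 2, hyperz_T2 = 0)
  out
}
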