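# Shared fixtures, built once per test run.

# Small 3-cohort simulation for unit tests (fast; default drivers).
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$ds)) {
    cfg <- sim_config(n_cohorts = 3, n_normal = 10, n_cancer = 40,
                      n_genes = 60, n_ee = 10,
                      n_cgi_regions = 40, n_opensea_regions = 40,
                      seed = 101L)
    .small_sim_cache$ds <- simulate_pan_cancer(cfg)
  }
  .small_sim_cache$ds
}

# Expression/methylation matrices as TSV text for IO tests.
write_tsv_matrix <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Independent greedy clustering re-implementation (oracle): plain loop over a
# position-sorted data.frame of one stratum, tracking cluster assignments.
oracle_cluster <- function(positions, max_gap = 500, max_width = 1500) {
  positions <- sort(positions)
  assign <- integer(length(positions))
  cl <- 1L
  anchor <- positions[1]
  assign[1] <- cl
  if (length(positions) > 1) {
    for (i in 2:length(positions)) {
      gap_ok <- (positions[i] - positions[i - 1]) <= max_gap
      width_ok <- (positions[i] - anchor) <= max_width
      if (gap_ok && width_ok) assign[i] <- cl
      else {
        cl <- cl + 1L
        anchor <- positions[i]
        assign[i] <- cl
      }
    }
  }
  split(positions, assign)
}

# Partial correlation oracle via the inverse of the joint correlation matrix:
# pcor(x, y | Z) = -Omega_xy / sqrt(Omega_xx * Omega_yy).
oracle_pcor_inverse <- function(y, x, Z) {
  M <- cbind(y = y, x = x, Z)
  Om <- solve(stats::cor(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}
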