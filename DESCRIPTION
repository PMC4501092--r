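Package: methylZ
Title: Methylation Instability Indices and Pan-Cancer Regulator Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-sample DNA methylation instability indices (HyperZ,
    HypoZ) from Illumina-450k-style beta matrices by regional clustering of
    probes and z-scoring against a normal-tissue reference; performs
    cross-cohort differential-expression and expression-index correlation
    meta-analyses with an analytic binomial consistency null; infers candidate
    methylome regulators by partial-correlation causal filtering and consensus
    networks; and assesses locus-level cross-cohort rank consistency. Includes
    a multi-cohort synthetic data generator with planted driver, confounded
    and mediated genes so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), limma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
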