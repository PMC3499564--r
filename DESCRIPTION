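Package: SpikeSlabGWAS
Title: Adaptive Multistep Metropolis-Hastings for Bayesian Variable
    Selection in Genome-Wide Association Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spike-and-slab Bayesian variable selection for continuous
    traits measured on genotyped individuals. Implements a sparse linear
    model with a parameter-expanded (noncentral-F type) prior on effect
    sizes and a beta-binomial prior on model size, sampled by
    Metropolis-Hastings kernels over the inclusion indicators: single-step,
    multistep sequential proposals with finitely adapted add/remove weights
    and move-size adaptation by expected jump distance, a delayed-rejection
    second stage that trims oversized multistep moves via incremental
    Cholesky updates, locus-neighborhood swap and toggle moves for
    linkage-disequilibrium structure, and Kohn-Smith-Chan and Nott-Kohn
    comparison kernels. Includes Rao-Blackwellized inclusion-probability
    estimation, effective-sample-size (Geyer initial monotone sequence) and
    potential-scale-reduction diagnostics, jump-distance move statistics,
    PLINK 1 binary genotype input/output, and a simulation module producing
    linkage-disequilibrium block genotypes with double-exponential effect
    sizes at a target proportion of variance explained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
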