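Package: chipchop
Title: Longitudinal Mutation Trajectories and CHIP/CHOP Stratification in
    NPM1-Mutated AML
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal variant-call data from
    NPM1-mutated acute myeloid leukemia sampled at diagnosis, complete
    molecular remission (CMR) and relapse. Implements cross-timepoint
    germline filtering by variant allele frequency (VAF), detection
    cutoffs, mutation-trajectory classification (lost/persistent/acquired
    and three-timepoint presence patterns), VAF-based clonal-hierarchy
    calls for NPM1 as a second-hit mutation, gene categorization into
    CHIP-like (clonal hematopoiesis of indeterminate potential) versus
    CHOP-like (oncogenic potential) sets with patient stratification at
    CMR and relapse, and survival analysis (Kaplan-Meier, log-rank, Cox
    proportional hazards) of the resulting strata. Includes a synthetic
    cohort simulator with ground truth and a deterministic reference
    fixture reconstructed from published aggregate counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
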