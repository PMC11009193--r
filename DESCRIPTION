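Package: buccalclock
Title: Simulated-Annealing Ensemble Epigenetic Clocks for Buccal Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds next-generation epigenetic aging clocks from buccal
    methylation arrays. CpG probes are quality-filtered, clustered by
    methylation pattern and averaged on the M-value scale; linear age models
    over cluster subsets are trained by simulated annealing under a
    multi-objective score combining chronological-age accuracy, the
    significance of delta-age associations with lifestyle and health factors,
    and model complexity; the top-scoring models are combined into a weighted
    ensemble with an age-bias rotation. Includes a seedable synthetic-cohort
    generator with planted age, lifestyle and cell-composition structure, a
    replicate-aware cross-validation harness, the clock metric suite (RMSE,
    MAE, R2, MAB, MRE), delta-age association modelling with FDR control, an
    elastic-net baseline, and descriptive methylome analyses (age-binned
    mean/variance trajectories, factor correlation overlap, genomic-context
    enrichment, differential variability).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    glmnet,
    pracma,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
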