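Package: netprior
Title: Genetics-Led Target Prioritization and Network Analysis
Version: 0.1.0
Authors@R: person("Netprior", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evidence-seeded network propagation for genetics-led drug-target
    prioritization, with downstream analyses: one-sided Fisher gene-set
    enrichment and rank-based target set enrichment with leading-prioritization
    extraction, maximum-scoring pathway-crosstalk subnetwork discovery with a
    degree-preserving permutation null, combinatorial node-removal analysis for
    drug-combination selection, targeted-attack robustness curves, drug
    repurposing by maximum clinical phase, and supra-hexagonal self-organizing
    map comparison of prioritizations across diseases.  Ships a synthetic-data
    generator with planted ground truth so the whole pipeline is exercisable
    and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
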