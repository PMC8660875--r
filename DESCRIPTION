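Package: flunet
Title: Group Semantic Networks from Verbal Fluency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates group-level semantic networks from category verbal
    fluency transcripts and compares them between two groups. Responses are
    normalized and tabulated into binary participant-by-exemplar matrices,
    filtered by minimum occurrence, equated across groups, converted to
    cosine association matrices, and sparsified with the triangulated
    maximally filtered graph (TMFG). Network structure is summarized by the
    mean local clustering coefficient, the average shortest path length, and
    Louvain modularity, and compared against Erdos-Renyi random-graph null
    ensembles and between groups with a case-wise participant bootstrap.
    Also includes the accompanying behavioral group statistics (pooled and
    Welch t tests from raw data or published summaries, chi-square tests on
    2x2 tables, Pearson correlations) and a synthetic cohort generator based
    on censored random walks over planted-partition graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0), car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
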