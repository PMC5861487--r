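Package: regennet
Title: Dynamic Protein-Protein Interaction Network Inference from Regeneration Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers condition-specific protein-protein interaction (PPI) networks
    from short time-course expression data. Candidate interactomes are built by
    projecting a human PPI edge list onto another species through an ortholog
    table and restricting it to differentially expressed proteins (one-way ANOVA
    with Bonferroni correction after upper-quartile normalization). Each
    candidate interaction is then validated against a discrete-time linear
    dynamic model fitted by constrained least squares on a cubic-spline
    densified time grid, and pruned by minimizing Akaike's information
    criterion over model order. Refined networks from several conditions can be
    compared to extract core proteins, induced core networks, condition-specific
    proteins and hub rankings. A synthetic-data generator simulating the dynamic
    model makes every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
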