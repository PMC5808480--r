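Package: enstab
Title: Elastic-Network Ensembles, Hydrogen-Bond Stability and Mechanical
    Stiffness for Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for comparing protein variants through
    elastic-network (anisotropic network model) ensembles. Generates
    conformer ensembles along low-frequency normal modes, scores
    hydrogen-bond stability as the fraction of conformers in which each
    bond is formed (SEA), detects bonds whose stability deviates most
    from the wild type ("destructive" bonds) via a contribution/histogram
    procedure with mean-shift clustering, computes pairwise mechanical
    stiffness maps with tail extraction and widest-path impulse routes,
    and provides the supporting statistics (mean-shift, hierarchical
    outlier ranking, Kolmogorov-Smirnov, Benjamini-Hochberg,
    position-occupancy correlation, hypergeometric list intersection).
    Includes generators for synthetic structures, stability tables and
    survival data so every stage can be exercised without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
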