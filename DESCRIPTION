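Package: percussr
Title: Surface Morphometry and Assemblage Statistics for Percussive Stone Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies percussive use-wear on primate and hominin stone tools
    from 3D surface scans. Detects discrete impact pits on the active surface of
    hammerstones and anvils with a topographic position index (TPI), measures
    their depth below the encompassing convex hull, gradient and surface
    roughness, derives 2D planform measures (pitted area percentage, pit
    density, distances of pits to the surface centre and edge, oriented
    bounding boxes), and compares assemblages with nonparametric statistics
    (Mann-Whitney U with exact small-sample p-values, Kruskal-Wallis, Dunn's
    post hoc test with Bonferroni correction) and principal component analysis.
    Ships the Djouroutou (Tai National Park) per-tool tables as fixtures and a
    synthetic surface/assemblage generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    polyclip,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, deldir
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
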