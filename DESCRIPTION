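Package: microperm
Title: Darcy Permeability Tensors and Perfusion from Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based continuum-flow modeling of three-dimensional
    microvascular networks. Computes Darcy permeability tensors of vascular
    graphs by solving Poiseuille nodal-pressure systems on mirrored, spatially
    periodic domains; preprocesses anatomical networks (connected-component
    density filtering, border elongation, blind-end pruning, representative
    elementary volume gating); fuses per-subnetwork tensors with
    surface-weighted, overlap-corrected averaging; incorporates empirical blood
    rheology (in-vitro apparent viscosity and red-cell phase separation at
    bifurcations); derives myocardial blood flow and arteriole-venule pressure
    drops; and simulates vascular remodeling scenarios (dilation, constriction,
    pruning). Includes seeded generators for synthetic capillary beds with
    known closed-form tensors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
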