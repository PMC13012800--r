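Package: phylospread
Title: Dispersal Statistics, Simulators and Landscape Hypothesis Tests for
    Continuous Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes posterior samples from Bayesian continuous
    phylogeographic inference. Parses BEAST-style annotated NEXUS trees whose
    nodes carry geographic coordinates, decomposes each tree into a table of
    per-branch movement vectors, and from those tables estimates lineage
    dispersal statistics (weighted dispersal velocity, weighted diffusion
    coefficient, wavefront distance through time, isolation-by-distance
    signal), builds kernel-density highest-posterior-density uncertainty
    polygons per MCC node or per time slice, simulates relaxed-random-walk
    dispersal along birth-death or fixed phylogenies, and tests the impact of
    environmental rasters on lineage diffusion velocity, dispersal location
    and isolation-by-resistance via tree-branch randomisation null models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    geosphere,
    igraph,
    Matrix,
    MASS,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geo-utils.R'
    'extraction.R'
    'dispersal-stats.R'
    'raster.R'
    'distances.R'
    'tree-io.R'
    'simulators.R'
    'fixtures.R'
    'hpd-regions.R'
    'landscape-tests.R'
    'phylospread-package.R'
    'randomisation.R'
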