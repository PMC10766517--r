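Package: ca1scaffold
Title: Scaffold Model Construction for the Hippocampal CA1 Region from
    Stained Section Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds full-scale "scaffold" models of a hippocampal CA1
    region from cell-body-stained histological section stacks: dynamic
    Otsu segmentation of somas into 3D coordinates, pruning and
    excitatory/inhibitory class assignment with seven interneuron
    classes placed by landmark geometry, voxel density analysis with
    transversal and antero-posterior gradient statistics, geometric
    axonal and dendritic probability clouds (cones, ellipsoids and
    surface-following tubes), touch-detection connectivity by
    bounding-box prefilter plus convex-hull inclusion with pruning to
    class-pair connection targets, and network-topology validation via
    degree, connection-length and Kullback-Leibler statistics. Includes
    a synthetic "mini-CA1" generator with known ground truth so the
    whole pipeline runs at desk scale, and exporters for placement text
    files and HDF5 connectomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RANN,
    rhdf5,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
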