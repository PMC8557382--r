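Package: crownshy
Title: Quantifying Crown Shyness from LiDAR Point Clouds via 3-D
    Surface Complementarity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies crown shyness -- the tendency of neighbouring tree
    crowns to avoid growing into each other -- from terrestrial laser
    scanning point clouds of individual trees.  Crowns are separated from
    boles with a vertical point-density profile, the facing parts of two
    crowns are isolated by a two-way nearest-neighbour search and an
    oriented bounding box, crown surfaces are reconstructed as regularized
    3-D alpha shapes (built on an internal Bowyer-Watson Delaunay
    tetrahedralization), and the surface complementarity statistic Sc of
    Lawrence and Colman is computed from matched face normals.  Includes
    tree-pair slenderness allometry, the associated group and regression
    statistics, a synthetic crown-pair generator with known ground truth,
    and readers/writers for XYZ, PLY and OBJ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RANN,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
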