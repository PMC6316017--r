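Package: depthvol
Title: Food Volume Estimation from Paired Depth Views
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Estimates the volume of small objects (portion-size estimation in
    dietary assessment) from a single metric depth image by synthesising the
    depth map seen from the opposite viewing angle, fusing the two views into
    one world-frame point cloud under a 180-degree rotation camera model with a
    translation-only iterative closest point refinement, and measuring volume
    by alpha-shape surface reconstruction. Includes a synthetic depth-pair
    renderer (ray casting against triangle meshes of analytic primitives), a
    compact encoder-decoder depth view-synthesis model with an inception
    variant and extrinsic-translation head, and an end-to-end evaluation
    protocol reporting per-object mean volume, spread and percent error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RANN,
    igraph,
    jsonlite,
    png,
    digest,
    reticulate,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
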