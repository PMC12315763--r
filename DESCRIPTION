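Package: calvaria
Title: Skull Bone Density and Subcutaneous Adiposity Proxies from T1-Weighted Head MRI
Version: 0.1.0
Authors@R: person("Calvaria", "Maintainers", email = "maintainers@calvaria.dev", role = c("aut", "cre"))
Description: Extracts proxy measures of skull bone mineral density, skull bone
    thickness, and intensity- and thickness-based subcutaneous adiposity from a
    T1-weighted head MRI together with a six-class tissue segmentation (grey
    matter, white matter, CSF, skull, soft head tissue, background).  Provides
    morphological correction of the skull segment, exact anisotropic Euclidean
    distance-transform thickness maps, a mid-skull surface built from a
    percentage position map with cortical/marrow intensity separation, a
    procedural calvarial sector atlas with a defacing-safe bone mask, Gaussian
    mixture intensity composites, and the reliability statistics (ICC with
    absolute agreement, Spearman correlations with Holm correction) used to
    evaluate the measures.  A layered ellipsoidal head-phantom generator with
    known ground truth makes the full pipeline testable without access to
    restricted imaging cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
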