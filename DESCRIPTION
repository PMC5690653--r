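Package: tubulometry
Title: Tubule Histomorphometry for Renal Medullo-Papillary Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative histomorphometry of tubular structures
    (mineralized tubules, iodine-stained vasculature, patent lumina) in
    micro-CT volumes of the renal medullo-papillary complex. Segments
    tubules by density thresholding and void inversion, labels connected
    components in 3D, reslices label volumes perpendicular to the common
    tubule axis, and measures per-tubule diameters as the minor axis of
    the minimum-area enclosing ellipse of each cross-section. Includes
    two-channel co-localization statistics, zone-wise diameter
    distributions with mode detection, a synthetic voxel-phantom
    generator with ground truth for validation, and TIFF/JSON/CSV input
    and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
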