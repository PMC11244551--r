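Package: epmap
Title: Analysis of High-Density Electro-Anatomical Maps of the Right Ventricle
Version: 0.1.0
Authors@R:
    person("epmap", "developers", email = "epmap@example.org", role = c("aut", "cre"))
Description: Feature extraction and 3D parametric mapping for catheter-based
    high-density electro-anatomical mapping (HDEAM) studies of the right
    ventricle, as used in Brugada-syndrome electrophysiology. Computes
    per-point unipolar electrogram features (J-point elevation, activation
    time, activation recovery interval with Bazett correction, peak-to-peak
    voltage), interpolates them onto a triangulated chamber surface,
    supports polygonal region-of-interest selection on the mesh, pairs
    pre/post drug-challenge acquisitions to build differential maps, and
    quantifies threshold-exceeding surface areas. Includes a native HDF5
    study container, OpenEP-style MAT (v7.3) import, VTK export, and a
    synthetic study generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rhdf5,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
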