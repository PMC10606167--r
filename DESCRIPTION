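Package: tavimetrics
Title: Automated Morphometry of the Aortic Valvular Complex for TAVI Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the 22 clinical measurements of the aortic valvular
    complex used in pre-procedural planning of transcatheter aortic valve
    implantation (TAVI) from a closed triangular surface mesh of the aortic
    root and left ventricle together with five anatomical landmarks (the two
    coronary ostia and the three leaflet nadirs). Provides centerline
    extraction by Laplacian-based contraction with a cross-section marching
    fallback, plane-mesh intersection with full per-section metrics (area,
    perimeter, centroid-chord minimum and maximum diameters, area- and
    perimeter-derived diameters), construction of the annulus, left
    ventricular outflow tract, sinus of Valsalva and sinotubular junction
    planes, per-sinus diameters and coronary heights, deterministic
    post-processing of landmark mask volumes into world coordinates, a
    parametric synthetic aortic-root phantom generator with analytic ground
    truth, and expert-agreement statistics (confidence intervals, mean
    absolute relative error, Pearson correlation, Bland-Altman limits of
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
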