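Package: astrocr
Title: Quantitative Pipelines for Caloric-Restriction-Induced Astrocyte Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for characterizing diet-induced remodeling of
    hippocampal astrocytes: leaflet volume-fraction estimation from radial
    fluorescence profiles, Sholl branch morphometry with coherence-enhancing
    diffusion filtering, gap-junction dye-coupling length-constant fitting,
    connexin puncta segmentation with Delaunay spatial statistics, and
    decomposition of stimulus-evoked astrocytic and neuronal currents
    (potassium current, glutamate transporter current, NMDAR-EPSC charge
    transfer, LTP magnitude). A synthetic-data generator emulates every input
    modality with known ground truth, so each stage is testable end to end
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deldir,
    igraph,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
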