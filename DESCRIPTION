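Package: enfaceOCTA
Title: Orthogonal OCT and En-Face OCT Angiography Analysis of Laser-Induced
    Retinal Injury
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of laser-induced retinal injury
    from single high-density optical coherence tomography (OCT) volumes:
    ground-truthed synthetic OCT volume simulation (layered retina, three
    inner capillary plexuses plus choroid, multiplicative speckle, per-B-scan
    motion jitter, acute-injury and choroidal-neovascularization lesion time
    courses), B-scan motion registration, orthogonal reslicing, retinal
    surface segmentation, surface-referenced 60 um slab extraction, en-face
    structural vessel enhancement and angiogram segmentation with projection
    artifact suppression, color depth-coded projections, lesion morphometry
    with percent-change/derivative dynamics and steady-state detection,
    plexus-resolved vessel density with non-perfusion interval detection,
    and acute-versus-CNV lesion classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Visualization, Preprocessing, Segmentation
RoxygenNote: 7.3.3
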