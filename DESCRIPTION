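Package: VesselQuant
Title: Automated Vascular Pattern Characterization for Contact Endoscopy
    with Narrow Band Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the level of disorder of superficial vascular
    patterns in contact-endoscopy narrow-band-imaging (CE+NBI) frames of
    the laryngeal mucosa. A frame is detrended with a Daubechies-7 wavelet
    decomposition, vessels are enhanced with a multiscale Frangi
    vesselness filter and reduced to one-pixel-wide skeletons by
    iterative thinning. Five per-image indicator signals (gradient
    direction histogram, rotational image averaging, per-segment angle
    and distance profiles, and digital curvature) are summarized into 24
    scalar features that feed four supervised classifiers (polynomial and
    RBF support vector machines, k-nearest neighbours, random forest)
    with grid search and stratified tenfold cross-validation. A synthetic
    image generator emulates the three clinical disorder grades (ordered
    parallel vessels, wavy vessels, IPCL-like loops) so the whole
    pipeline can be exercised and benchmarked without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    tools,
    methods,
    stats,
    utils,
    EBImage,
    signal,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, ImageProcessing, Classification, FeatureExtraction
RoxygenNote: 7.3.3
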