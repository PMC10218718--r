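Package: tsrslide
Title: Automated Tumor-Stroma Ratio Estimation from H&E Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the tumor-stroma ratio (TSR) of
    hematoxylin-eosin stained colorectal-cancer slide images. Implements
    Macenko stain normalization from the optical-density point cloud, Otsu
    tissue masking, sliding-window tiling with annotation- and tissue-coverage
    filters, a three-class (tumor/stroma/other) patch classifier with
    pluggable backbones and three transfer-learning setups, the patch-count
    TSR statistic with stroma-high/low dichotomization, and the evaluation
    statistics used to benchmark automated TSR against visual pathologist
    scoring (per-class precision/recall/F1, Pearson correlation, standard
    error of the estimate, Cohen's kappa). A synthetic-slide generator based
    on Beer-Lambert stain mixing provides H&E-like slides with exact ground
    truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
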