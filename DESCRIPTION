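Package: shootcount
Title: Semi-Supervised Density-Map Counting of Conifer New Shoots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the number of current-season new shoots in
    top-down RGB images of slash pine (Pinus elliottii) crowns from
    sparse point annotations. Implements a mean-teacher semi-supervised
    counting network: geometric adaptive Gaussian density maps built
    from point labels, patch-aligned random masking of unlabeled
    images, a dilated VGG-style multiscale feature extractor with
    attentional feature fusion, multiscale dilated-convolution
    regression and classification heads, the combined structural /
    total-variation / cross-entropy / consistency loss, exponential
    moving-average teacher updates, and MAE/RMSE counting evaluation.
    Includes a synthetic scene generator emulating dense small bright
    shoots on textured crown backgrounds so the whole pipeline runs at
    desk scale on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    rhdf5,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
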