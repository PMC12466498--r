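Package: cagedetect
Title: Occlusion-Aware Detection of Caged Poultry with Multi-Scale Edge and Context Modules
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting caged chickens in low-light, heavily occluded
    housing imagery. Implements an anchor-free single-class detector substrate
    (CSP stages, SPPF, attention stage, decoupled head with distribution-focal
    box regression) together with three occlusion/illumination-oriented blocks:
    a multi-scale edge information extractor (pooling pyramid, high-frequency
    residual enhancement, dual-domain spatial/frequency selective attention),
    context-guided downsampling, and a multi-scale separation-and-enhancement
    attention detection head. Includes the HSV/gamma/CLAHE/bilateral annotation
    enhancement pipeline with filename-matched label transfer, a procedural
    generator of caged-scene images with YOLO-format head-neck labels, dataset
    split arithmetic, training with SGD and online augmentation, and a full
    precision/recall/F1/mAP evaluator with radar-chart normalization. The
    network stack (layers, autograd, SGD, parameter and FLOP profiling) is
    implemented natively in R with Rcpp kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
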