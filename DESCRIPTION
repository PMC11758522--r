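Package: cementochron
Title: Cementochronology of Growth, Life Span and Life History from
    Incremental Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating life spans, annual growth rates and
    life-history parameters from grayscale images of dental cementum.
    Detects circum-annual light increments along radial grayscale
    transects with a segment-wise mean-plus-SD rule, measures growth
    layer group widths, converts widths to mass-specific growth rates,
    fits and selects nonlinear growth models by AIC, locates the
    growth-rate truncation window used as a proxy for sexual maturity,
    computes areal surface-texture features of cementum patches with
    juvenile/adult discrimination via ANOVA screening, PCA and convex
    hull comparison, and links life span to metabolic rate through
    phylogenetically informed regression. Includes a synthetic cementum
    image generator with ground-truth sidecars for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    EBImage,
    grDevices,
    jsonlite,
    lhs,
    minpack.lm,
    phytools,
    stats,
    tiff,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
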