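Package: stentorquant
Title: Quantification of Macronuclear Shape Change in Stentor coeruleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the macronuclear shape-change cycle of the
    giant ciliate Stentor coeruleus from calibrated 2D silhouettes and
    fluorescence images. Estimates macronuclear volume from binary silhouette
    masks by a solid-of-revolution (stack-of-cylinders) model, segments and
    counts macronuclear nodes by watershed on the distance transform, computes
    node morphometrics (circularity, equivalent diameter, rotational-symmetry
    controls), builds event-aligned time courses of volume, node count and
    volume per node with t-based 95% confidence bands, and quantifies
    fluorescent puncta (rolling-ball background subtraction, moment-preserving
    thresholding, watershed separation, size and intensity gates). A synthetic
    beads-on-a-string nucleus generator with closed-form ground-truth volume,
    a coalescence-cycle time-course simulator and a puncta image generator
    make the full pipeline testable without raw microscopy data. Includes a
    small two-sample statistics battery (Welch's t from raw data or summary
    statistics, two-sample Kolmogorov-Smirnov, Mann-Whitney U with exact
    small-sample null, mean with 95% confidence interval).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
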