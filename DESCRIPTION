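Package: netlapse
Title: Quantification of NET Formation and Degradation from Two-Channel
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel classification of live-cell Sytox/Hoechst time-lapse
    videos into background, netotic and necrotic regions from the shape of
    each pixel's background-rescaled intensity trace; peak-aligned median and
    quartile decay curves with 50 percent and 80 percent lifetime (half-life)
    estimation for neutrophil extracellular trap (NET) degradation; area-gated
    cell census and per-cell net-span metrics; and a seeded synthetic video
    generator with ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
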