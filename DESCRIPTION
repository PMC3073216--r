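Package: slideroi
Title: Example-Driven Region-of-Interest Scoring for Virtual Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects regions of interest in large histology images (virtual
    slides) from a single positive and a single negative example block chosen
    by the user. The slide is partitioned into a grid of equal-size blocks;
    each block is described by five low-level histograms (gray level, RGB
    color, local binary pattern, Tamura texture, Sobel gradient magnitude);
    per-feature distance maps to the example blocks are computed under five
    histogram metrics, normalized, weighted by a peak-promotion operator and
    integrated into a single relevance map. Includes tooling to parse
    slide-navigation logs (window-of-interest request sequences), derive
    per-block visit counts and evaluate a relevance map against them with
    precision and recall, a random-selection baseline, and a synthetic
    H&E-like slide generator with block-level ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    tiff,
    jpeg,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
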