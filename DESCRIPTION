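Package: phenoroi
Title: Automated Region-of-Interest Extraction for Phenological Camera Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts phenologically informative regions of interest (ROIs) from
    fixed-view camera image time series. Computes green chromatic coordinate
    (%greenness) series for pixels and ROIs, grows semi-supervised ROIs from
    seed "pinpricks" by thresholding per-pixel correlation images (sROI), and
    segments images without supervision via truncated singular value
    decomposition of the pixel-channel by time data matrix followed by k-means
    clustering (uROI). Candidate ROIs are ranked by two optimality criteria: a
    structural change-point supF statistic over the spring window (OC1) and the
    best Pearson correlation against a bank of piecewise-linear seasonal
    templates (OC2), from which rough start- and end-of-season dates are
    derived. Includes a ground-truthed synthetic scene generator for testing
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    irlba,
    stats,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
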