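Package: shiftscan
Title: Detecting Separate Time Scales in Replicate Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects biological processes operating on time scales other than
    the measured one in replicate gene-expression time courses. Each gene's
    series is converted to a rank permutation; similarity between replicates
    is scored at integer temporal shifts by a normalized sum of absolute rank
    differences over the shrinking overlap window, with one-sided p-values
    from a Gaussian null for uniformly random permutations whose moments
    follow from the difference of two continuous uniform variables. Genes are
    classified by their most significant shift. Also provides linear-spline
    resampling onto common time grids, exhaustive and Monte-Carlo calibration
    of the Gaussian null, hierarchical co-expression clustering cut at a
    Pearson correlation threshold, hypergeometric gene-set enrichment,
    Fisher's method for combining shift p-values across three or more
    replicates, and a synthetic-data generator with embedded ground-truth
    shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
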