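Package: evireg
Title: Evidential Fusion of Candidate Transformations for Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registration of grayscale image pairs by evidential reasoning.
    Candidate projective transformations are produced either by sparse
    keypoint pipelines (corner/blob detection, ratio-test matching,
    MSAC/RANSAC mismatch removal, least-squares homography estimation) or by
    dense rigid search maximizing mutual information, normalized
    cross-correlation or peak signal-to-noise ratio.  The candidates form a
    frame of discernment; basic belief assignments are built from normalized
    cross-correlation measured on three information channels (gray
    intensities, Canny edges, phase-angle reconstruction), combined with
    Dempster's rule or PCR6 proportional conflict redistribution, and the
    fused masses yield a combined transformation whose quality is scored by
    the average absolute intensity difference against a known ground truth,
    globally and on a 5x5 spatial partition.  A deterministic synthetic
    fixture generator provides textured image pairs with known rigid or mild
    projective ground truth, optionally corrupted by Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    tiff,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
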