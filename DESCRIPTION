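Package: flexalign
Title: Flexible-Particle Cryo-EM Processing by Signal Subtraction and
    Sub-Particle Recentering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-particle cryo-EM tools for large flexible complexes
    that defeat whole-particle alignment. Implements residual signal
    subtraction (removing the CTF-modulated projection of unwanted
    density from each particle image), sub-particle recentering into
    smaller boxes with per-particle defocus depth correction, reference
    projection matching (global and local), an eigenimage multivariate
    statistical analysis test for cyclic point-group symmetry of top
    views, and map-quality metrics (Fourier shell correlation, global
    and per-voxel local cross-correlation, B-factor sharpening).
    Includes a synthetic flexible-particle simulator (stacked C13 rings
    with a rocking hinge, CTF and noise) with ground truth for scoring
    alignment accuracy, plus STAR and MRC2014 readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
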