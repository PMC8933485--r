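Package: radphantom
Title: Simulated CT Acquisitions for Radiomics Stability Analysis
Version: 0.1.0
Authors@R:
    person("Radphantom", "Developers", email = "radphantom@example.org",
           role = c("aut", "cre"))
Description: A virtual-phantom computed tomography (CT) simulation
    environment for studying the stability and discriminative power of
    radiomics features. Provides a synthetic anthropomorphic abdominal
    phantom generator with annotated tissue regions, helical and circular
    cone-beam forward projection, Poisson sinogram noise with variance
    calibration, filtered back-projection (FDK-style) and SIRT
    reconstruction, extraction of 86 standard intensity and texture
    radiomics features (first order, GLCM, GLDM, GLRLM, GLSZM), rank-sum
    based stability and discriminative-power statistics, and PCA-based
    variability comparison between acquisition sets.
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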