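Package: tomohet
Title: Spatial Heterogeneity of Liver Stiffness from Multifrequency MR
    Elastography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end pipeline for quantifying the spatial heterogeneity
    of hepatic fibrosis with multifrequency magnetic resonance elastography
    (MRE). Simulates viscoelastic liver phantoms in two disease archetypes
    (heterogeneous focal stiffening versus homogeneous diffuse stiffening),
    synthesizes multifrequency shear-wave displacement fields, reconstructs
    shear-wave-speed (SWS) and fluidity (phi) maps by directional k-space
    filtering and amplitude-weighted wave-number compounding, computes
    volume-of-interest statistics (mean, SD, coefficient of variation),
    stages fibrosis by published SWS cutoffs, and compares cohorts with
    Welch t-tests, Pearson correlations, AUC with DeLong confidence
    intervals, and the APRI and Mayo risk score calculators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
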