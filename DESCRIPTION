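Package: gliogrow
Title: Anisotropic Reaction-Diffusion Glioma Growth Modeling and Inverse Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates glioma growth with an anisotropic Fisher-KPP
    reaction-diffusion model over voxelized brain geometries, builds tumor
    cell diffusion tensors from DTI-derived water tensors, generates
    synthetic tumor datasets with threshold-imaging contours, and estimates
    cell density and model parameters (infiltration length and front speed)
    by grid search and by small convolutional neural networks, with
    surface-distance evaluation metrics and forward forecasting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
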