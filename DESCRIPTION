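Package: napacool
Title: Postharvest Cold-Storage Modelling for Chinese Cabbage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the cooling of Chinese cabbage (Brassica rapa ssp.
    pekinensis) in cold storage. Classifies heads into size classes by
    K-means clustering with elbow and silhouette model selection, estimates
    molar respiration rates from sealed-chamber CO2 traces and converts them
    to metabolic heat, solves transient heat conduction in an equivalent
    porous sphere with a respiration source and Robin surface exchange,
    calibrates the surface heat-transfer coefficient by RMSE grid scan
    against cooling curves, and compares cold-room loading strategies with a
    lumped zonal compartment model. A synthetic-data generator reproduces
    the statistical structure of the underlying morphology, gas-exchange and
    cooling measurements so the whole chain is testable without sensor logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
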