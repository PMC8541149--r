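Package: sloshsim
Title: Reduced-Order Simulation of Epidural-Driven CSF Slosh in Canine
    Syringomyelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A one-dimensional coaxial-tube surrogate of transient
    cerebrospinal-fluid (CSF) and spinal-cord dynamics in the canine spinal
    canal under an epidural (Valsalva-like) pressure pulse.  The package
    synthesizes smooth cranio-caudal anatomy profiles, builds the 57-model
    suite of syrinx placement and expansion configurations (a syrinx-free
    baseline, 28 single small syringes, and 28 caudally expanding syringes),
    integrates the coupled subarachnoid-space/syrinx/cord equations with an
    explicit staggered-grid scheme, and post-processes axial stress into
    peak-over-time maps, 1 mm slice medians and the summary statistics
    (sigma_max, delta_sigma, percent increase) used to assess the "slosh"
    hypothesis of syrinx propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
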