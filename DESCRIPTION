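Package: memscape
Title: Energy-Landscape Models of Spatial Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and fits drift-diffusion models of spatial working
    memory on one-dimensional energy landscapes, including an
    activity-dependent plasticity variant in which the memory trace
    locally deforms the landscape as it moves. Provides the behavioral
    statistics used to characterise delayed-estimation data (target-binned
    bias profiles and their saturation curves, binned mutual information,
    kernel-weighted proactive-interference curves, bootstrap confidence
    intervals and empirical p-values), Monte-Carlo model fitting by
    Kullback-Leibler minimisation with a box-constrained pattern search,
    likelihood-based model comparison (AIC/BIC with bootstrap p-values),
    parameter-recovery and robustness studies, and a synthetic-data
    generator that emulates the delayed-estimation task structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
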