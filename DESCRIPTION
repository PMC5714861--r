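Package: recombkit
Title: Recombination Landscapes and Mapping Resolution in Biparental and
    Multi-Parent Crop Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the crossing schemes behind doubled-haploid (DH),
    recombinant inbred line (RIL), intermated (IBM) and eight-founder MAGIC
    maize populations, detects recombination breakpoints from marker
    haplotypes, and summarises recombination events, segment lengths and
    windowed recombination frequency. Builds pooled recombination-bin
    partitions under line and marker subsampling, fits power-law models of
    bin number and bin size against marker number, evaluates the closed-form
    relationship between per-line recombination events and achievable bin
    resolution, and measures QTL map resolution with null-phenotype LOD
    scans and 2-LOD support intervals. Includes a founder-assignment hidden
    Markov model for multi-parent populations and a deterministic
    end-to-end pipeline driver.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
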