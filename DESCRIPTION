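Package: tagpanel
Title: Tag SNP Panel Design for Custom Genotyping Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes the output of linkage-disequilibrium bin-tagging
    programs (ldSelect-style or tabular bin definitions) to design custom
    genotyping panels. Selects tag SNPs that maximize the probability of
    genotyping success under platform constraints (GoldenGate proximity
    conflicts, Infinium bead types) and user constraints (obligate and
    excluded SNPs, previously genotyped SNPs, functional-class preferences,
    multiple panels, multi-population bin sharing), using a lexicographic
    three-phase search per bin cluster with a time-budgeted exhaustive swap
    and a bounded approximate fallback. Includes a synthetic instance
    generator, a brute-force oracle, and a randomization-dominance
    validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
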