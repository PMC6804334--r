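Package: mitohet
Title: Mitochondrial Heteroplasmy Calling and Intratumor Spatial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects mitochondrial DNA substitutions and low-frequency
    heteroplasmies from strand-resolved per-site base counts using
    strand-concordant allele filtering and an exact binomial test against a
    noise floor, with a circular pseudo-reference to rescue read mapping
    across the replication origin. Includes a count-level read simulator for
    precision/recall evaluation, purity- and ploidy-corrected relative mtDNA
    copy-number estimation, construction and weighted Robinson-Foulds
    comparison of sample dendrograms built from spatial coordinates,
    heteroplasmy profiles, copy numbers and nuclear variants (with
    leaf-label permutation significance), and Nei-Gojobori style Ka/Ks
    selection statistics under the vertebrate mitochondrial genetic code.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, Biostrings, stats, utils
Suggests: testthat (>= 3.0.0), phangorn, withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
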