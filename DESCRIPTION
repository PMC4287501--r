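Package: palinreg
Title: De Novo Discovery of Palindromic Transcription Factor Binding
    Sites in Metagenomic Promoter Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts proximal promoter regions from long metagenomic
    reads using protein-alignment evidence, discovers transcription
    factor binding sites de novo as statistically overrepresented
    palindromic dimer motifs (W1-spacer-W2, where W2 is the reverse
    complement of W1) under a Poisson background model, and computes
    downstream regulatory-potential statistics: per-metagenome site
    densities, ranking of promoters into top-k percent regulatory bins,
    Fisher functional enrichment with Bonferroni correction,
    cross-environment comparisons, Kruskal-Wallis density tests, and
    window-shuffle randomization controls. Includes deterministic
    synthetic-data generators with planted ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    Biostrings
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
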