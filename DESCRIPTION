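Package: mitoarch
Title: Architecture and Annotation Refinement of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the architecture of circular insect
    mitochondrial genomes from a sequence plus a gene feature table:
    protein-coding gene boundary refinement under the invertebrate
    mitochondrial genetic code with truncated stop-codon designation,
    nucleotide composition with AT/GC strand-skew statistics, codon usage
    and relative synonymous codon usage (RSCU), intergenic spacer and
    gene-overlap accounting, gene-order rearrangement classification
    against the ancestral insect arrangement, control-region tandem-repeat
    and motif detection, tRNA stem pair accounting, and a synthetic
    mitogenome generator with ground-truth annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
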