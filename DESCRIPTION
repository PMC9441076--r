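Package: divscan
Title: Genome Scans of Coding-Sequence Divergence and dN/dS Between
    Diverging Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for contrasting the genomic architecture of
    coding-sequence divergence in the early and late stages of speciation.
    Transcript collections from two lineages are anchored on a reference
    genome through tabular alignment hits, filtered into single-locus
    orthologs by positional paralog classification, reduced to gap-free
    in-frame codon alignments by six-frame open-reading-frame extraction,
    and compared with pairwise counting estimators of synonymous and
    nonsynonymous substitution rates (Nei-Gojobori 1986 and Yang-Nielsen
    2000). Positive selection is assessed by codon bootstrap resampling of
    the dN - dS difference with false-discovery-rate control, and the
    resulting divergence landscape is characterized along scaffolds
    (divergence pattern classes, Fisher's index of dispersion of
    inter-divergent-gene distances, per-scaffold divergence/dN-dS
    correlations, genome-wide dN on dS regression). A fully synthetic data
    generator with a codon-level substitution simulator reproduces the
    statistical structure of both speciation regimes so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
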