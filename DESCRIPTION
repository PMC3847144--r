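Package: xenosig
Title: Compositional Screening for Horizontal Gene Transfer and
    Functional Divergence in Bacterial Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decide between horizontal gene transfer and gene
    loss for patchily distributed bacterial gene families.  Implements a
    per-gene compositional "alien signature" battery (GC content by codon
    position, 3:1 codon-junction dinucleotide relative abundances with the
    sigma difference and rank-covariation tests, relative synonymous codon
    usage with a chi-square test on 41 degrees of freedom, and the codon
    adaptation index as CAIobs/CAImax) together with the deviation rules
    used to flag atypical genes; reciprocal-best-hit ortholog detection
    from all-against-all protein similarity searches; type-I functional
    divergence between two protein subfamilies (maximum-likelihood theta,
    likelihood-ratio test, per-site posterior probabilities over Fitch
    parsimony substitution counts); and Fisher-exact / Student-t phenotype
    enrichment scans.  Ground-truth synthetic-genome, site-count and
    trait-table generators make every stage testable with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
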