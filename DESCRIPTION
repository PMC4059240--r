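Package: codonsfs
Title: Selection on Synonymous Codon Usage from Polymorphism Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify weak natural selection on synonymous
    codon usage from population resequencing data. Infers per-codon preference
    scores by factor analysis of per-gene codon usage, calls biallelic
    synonymous and intron polymorphisms from strain alignments with an
    outgroup, polarizes derived states by parsimony, and tests for shifts in
    the unfolded site frequency spectrum with respect to the change in codon
    preference (delta-pref), including a sum(d x delta-pref) permutation test
    and a variant robust to ancestral-state misassignment (ASM). Provides
    closed-form neutral, sequencing-error, and ASM null models, Watterson
    theta with degeneracy-weighted synonymous site counting, recombination
    rate binning and diversity/codon-bias contrasts, and a synthetic-data
    generator with a selected site-frequency-spectrum sampler for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
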