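Package: intronless
Title: Design of Intronless Mammalian Transgenes by Stochastic Synonymous Recoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts an intron-containing mammalian gene into an intronless
    (or first-intron-only) transgene by stochastically recoding synonymous
    sites toward a GC3 target model and an exonic-splice-enhancer (ESE)
    density target. Reads genes from GenBank or FASTA, removes introns
    (optionally keeping the first), scores synonymous codons under four GC
    strategies (position-dependent favourability curves for 1-2 exon genes,
    maximal GC, human codon usage, or ESE-only), adjusts ESE hexamer density
    in the vicinity of removed introns, protects restriction sites, avoids
    blacklisted motifs, generates a seeded variant cloud and reports the
    best-matching variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    seqinr,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
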