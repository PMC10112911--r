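Package: mutfunnel
Title: Mapping-by-Sequencing Candidate Mutation Identification for Haploid Mutant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the forward-genetics
    candidate-mutation funnel used to locate causal lesions in haploid,
    UV-mutagenised genomes: subtraction of variants shared with a panel of
    sibling mutant lines, quality filtering (depth band, mapping quality,
    call quality, alt-allele fraction, both-strand support), strand-aware
    codon-level effect annotation on GFF3 gene models, and intersection of
    CDS-hit genes across independent mutant strains.  Also provides
    Mendelian segregation testing (Yates-corrected goodness of fit),
    mutation-phenotype co-segregation checks, TPM-based expression gating
    with differential-expression set classification (exclusive expression
    and silencing), and transect line-profile peak counting for
    fluorescence microscopy.  A synthetic-data module generates every input
    the pipeline consumes (genomes with gene models, mutagenised strain
    variant sets, sibling-line panels, segregating families, count
    matrices, intensity profiles) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma,
    tiff,
    withr
Config/testthat/edition: 3
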