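Package: clonetrace
Title: Clonality Inference for Synchronous Multifocal Tumours from Multi-Sample Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether synchronous multifocal tumours within one organ are of
    clonal or field-effect origin from multi-region exome variant calls. Reads a
    multi-sample VCF (one normal plus two or more tumour samples), applies
    high-confidence filters (site filter status, per-sample supporting-read depth,
    known-site exclusion), encodes genotypes as a binary marker matrix, partitions
    markers into sharing classes (germline, trunk, private, mixed), builds BioNJ and
    UPGMA trees rooted on an all-reference pseudo-sample with bipartition bootstrap
    support, and tests tumour monophyly. Also classifies each variant's
    strand-collapsed dinucleotide/trinucleotide sequence context to quantify
    APOBEC-type TpC* mutagenesis, compares TpC* and functional-impact proportions
    between sharing classes with exact 2x2 tests, intersects functional tumour
    variants with a candidate driver gene list, and ships a synthetic multifocal
    patient generator (reference FASTA, multi-sample VCF, truth tables) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
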