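Package: vtquant
Title: Homolog-Based Virtual Transcript Quantification for De Novo Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies and compares RNA-seq expression for organisms without a
    reference genome. Assembled contigs are clustered by their best homology
    hit into "virtual transcripts" that serve as a shared reference across
    datasets; per-dataset read counts (RC), estimated RPKM (eRPKM) and
    estimated TPM (eTPM) are computed per virtual transcript, and Gene
    Ontology terms can be summarized cumulatively at a chosen hierarchy
    level. Includes readers for FASTA, BLAST outfmt-6 tabular hits, SAM/BAM
    or count TSV mappings, OBO ontologies and GO association tables, a
    deterministic synthetic-fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
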