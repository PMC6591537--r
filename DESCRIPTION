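Package: dhmine
Title: Mining and Processing of CAPA/PBAN/DH Neuropeptide Precursor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and characterising
    pyrokinin/CAPA/PBAN-family neuropeptide precursor genes of the kind that
    encode insect diapause hormone (DH). Provides six-frame translation and
    ORF finding, local-alignment screening of genomic contigs with a
    conserved C-terminal motif filter (FGPR[VIY]), prohormone processing at
    GR/GRR/KR endoproteolytic sites with C-terminal amidation and
    N-terminal pyroglutamate handling, C-terminal motif classification of
    mature peptides into DH types I-V with tandem-repeat detection and
    sequence-logo information content, theoretical monoisotopic mass
    computation and ppm-tolerance matching to observed LC-MS/MS masses,
    codon-usage bias indices (CAI, CBI, FOP, GC3s), Poisson-corrected
    neighbor-joining phylogeny with bootstrap support, and the bioassay
    statistics used in diapause studies (diapause incidence, 2^-ddCt
    relative expression, ANOVA with Tukey/Duncan letter groupings).
    Synthetic-data generators emit every input format with machine-readable
    ground truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
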