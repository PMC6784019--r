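Package: knotminer
Title: Proteo-Transcriptomic Mining of Disulfide-Rich Venom Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates venom-gland transcriptome assemblies with mass
    spectrometry observations to identify and classify disulfide-rich
    toxin precursors. Provides six-frame translation and ORF extraction,
    heuristic signal/propeptide cleavage to recover mature peptides,
    cysteine-framework extraction and superfamily classification with
    domain-signature matching (WAP, SVWC, astakine), theoretical
    monoisotopic mass computation under post-translational modification
    sets with MALDI mass-list matching and C-terminal amidation
    inference, Smith-Waterman mapping of de novo MS/MS fragments onto
    translated transcripts with coverage computation, rational toxin
    nomenclature, and a seeded synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Transcriptomics, SequenceMatching
RoxygenNote: 7.3.3
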