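Package: byssomap
Title: Proteotranscriptomic Fingerprinting of Mussel Byssal Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for fingerprinting secreted byssal (adhesive)
    proteins of the quagga mussel (Dreissena bugensis) from a de novo foot
    transcriptome and LC-MS/MS peptide-spectrum matches. Performs six-frame
    translation and ORF extraction of assembled transcripts, in-silico tryptic
    digestion and modification-aware peptide-to-protein mapping with spectral
    counting and coverage, applies score/homology/signal-peptide candidate
    filters, and characterizes accepted mature proteins (average mass,
    Henderson-Hasselbalch charge and isoelectric point, amino-acid composition
    and category, Kyte-Doolittle hydropathy, terminal-block pIs, tandem repeats
    and degenerate motifs). Ships the published Dreissena bugensis foot protein
    (Dbfp) reference sequences and a seeded synthetic-data generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
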