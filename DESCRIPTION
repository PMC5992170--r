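Package: pprkit
Title: Design and Analysis of Consensus Pentatricopeptide-Repeat (cPPR)
    Proteins for Sequence-Specific ssDNA and RNA Targeting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the modular pentatricopeptide-repeat (PPR)
    base-recognition code for designing consensus PPR (cPPR) proteins
    against arbitrary single-stranded DNA or RNA targets. Provides
    forward design (target sequence to protein sequence) and reverse
    engineering (protein sequence to predicted target), mismatch-aware
    binding-site scanning, telomeric-primer annotation, a desk-scale
    Bind-n-Seq analysis pipeline (anchored flank trimming, per-position
    base frequencies, exact-test k-mer enrichment, sequence-logo
    information content) with a matched synthetic library simulator, and
    structural metrics for PPR solenoids (hydrogen-bond detection,
    inter-repeat junction networks, superhelix compaction) from PDB
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
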