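Package: saavtrace
Title: Plasma Proteogenomics: Variant Peptide Detection and Placental
    Transfer Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for plasma proteogenomics built around single amino
    acid variant (SAAV) peptides. Constructs variant tryptic peptide
    databases from protein sequences and SNP annotations, predicts peptide
    isoelectric points for high-resolution isoelectric focusing (HiRIEF)
    fraction mapping, curates variant spectra with a flanking fragment-ion
    check, classifies SNP-array genotypes and establishes genomic support
    for detected variant peptides, and infers transfer of variant proteins
    between mother and newborn across the placenta. Includes label-free and
    isobaric-label quantification conventions (top-3 MS1 protein areas,
    median PSM-ratio quantification, picked target-decoy FDR), replicate
    coefficient-of-variation summaries, and a synthetic-data generator that
    emulates the mother-child study design so the full pipeline is testable
    without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
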