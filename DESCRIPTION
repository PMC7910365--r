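Package: paleopept
Title: Authentication of Ancient Food Peptides in Pottery Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-identification authentication analysis for shotgun
    paleoproteomics of archaeological pottery residues. Reads protein
    databases (FASTA) and peptide evidence tables (MaxQuant-style TSV or a
    generic CSV dialect), quantifies asparagine and glutamine deamidation
    as an intensity-weighted percentage with bootstrap confidence
    intervals, classifies peptide termini as tryptic, aspecific-enzymatic
    (after Tyr/Trp/Phe) or diagenetic non-enzymatic (after Asn/Asp/Gln/Glu),
    groups protein identifications by parsimony with coverage and
    unique-peptide counts, applies score/coverage/uniqueness validity
    filters, and contrasts food-derived against contaminant peptide
    classes. A ground-truthed synthetic evidence generator emulating
    degraded ancient proteomes is included so the whole pipeline is
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
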