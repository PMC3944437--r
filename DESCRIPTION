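Package: xenomatrisome
Title: Species-Resolved Matrisome Signatures from Tumor Xenograft Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to deconvolve the tumor and stromal contributions to the
    extracellular matrix (ECM) of human-in-mouse xenograft tumors from
    label-free shotgun proteomics. Peptide-spectrum matches searched against a
    combined human+mouse database are filtered by per-charge target-decoy
    false-discovery-rate thresholds, collapsed to distinct peptides, grouped
    into protein subgroups via shared peptides, annotated against the
    matrisome, and quantified by summed precursor-ion intensity of
    species-specific peptides. A fivefold dominance rule assigns each protein
    a tumor (human) or stroma (mouse) origin, and per-tumor-type matrisome
    signatures are compared between tumors of differing metastatic potential.
    A ground-truthed synthetic-data generator simulates ortholog proteome
    pairs and PSM tables so every stage of the pipeline can be validated
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
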