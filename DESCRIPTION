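Package: pepfunnel
Title: Computational Screening Funnel for Designed GLP-1 Receptor Agonist Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Triage of large pools of designed GLP-1 receptor agonist
    peptide candidates through sequential stability, efficacy and
    diversity gates. Provides template-numbered peptide records with
    non-canonical residue tokens (e.g. Aib), FASTA I/O, conservation
    analysis and design-mask construction; NEP-24.11 cleavage-site
    scanning and physicochemical scoring (net charge, isoelectric point,
    hydrophobicity, helix propensity); structure-quality metrics against
    a reference complex (Kabsch superposition, C-alpha RMSD, TM-score,
    Shrake-Rupley solvent accessibility, spatial aggregation propensity,
    mean pLDDT, interface predicted aligned error); neighbor-joining
    diversity clustering with representative selection and a
    patent-similarity cap; and assay-table bookkeeping (relative
    expression, label tallies). A synthetic-data module generates
    template-constrained candidate pools, ideal alpha-helical structures
    and mock confidence files so the whole funnel is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
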