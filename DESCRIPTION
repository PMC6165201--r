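Package: peptaibio
Title: Peptaibiome Analysis: De Novo MS Sequencing, Annotation,
    Quantitation and Conformational Statistics of Peptaibols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the peptaibiome of filamentous fungi from
    HPLC-ESI-MS data. Implements residue-level mass chemistry for peptaibols
    with non-proteinogenic residues (Aib, Iva, C-terminal 1,2-amino alcohols),
    sodiated-adduct deconvolution, de novo sequence assembly from b-ion ladders
    and MS2-resolved y7 fragments, similarity annotation against a database of
    known peptaibols, external-standard calibration and quantitation, and
    conformational-ensemble statistics (Ramachandran free-energy surfaces,
    backbone hydrogen-bond and turn classification, RMSD and radius-of-gyration
    landscapes). Ships seeded generators for synthetic peak lists and helical
    backbone ensembles so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
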