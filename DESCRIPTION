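Package: nitrotox
Title: Structure-Activity Grouping and In Vitro (Geno)Toxicity Analytics for
    beta-Nitrostyrene Derivatives
Version: 0.1.0
Authors@R:
    person("ITEM", "Toxinformatics", email = "toxinformatics@example.org",
           role = c("aut", "cre"))
Description: Tools for fingerprint- and descriptor-based grouping of a
    beta-nitrostyrene compound panel (PubChem/CACTVS 881-bit substructure
    keys, MACCS keys, hashed circular and linear-path fingerprints, Tanimoto
    similarity, Lipinski rule-of-five and Ghose screening with Crippen LogP
    and Ertl TPSA computed from SMILES), together with the analysis
    mathematics of four in vitro toxicity assays: LDH/WST-1 plate
    cytotoxicity normalization, alkaline comet assay tail-intensity
    summarization, gammaH2A.X / pH3(S10) nucleus classification, and the
    complete OECD TG 490 mouse lymphoma assay calculation chain (suspension
    growth, microwell cloning efficiency, mutation frequency, Global
    Evaluation Factor relevance call, validity criteria). Includes one-way
    ANOVA with Dunnett many-to-one comparisons and seeded synthetic-data
    generators for every assay so the full pipeline is testable without raw
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
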