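Package: ChemokineBias
Title: Ligand Bias Quantification and Chemokine Recognition-Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies biased agonism at chemokine receptors from
    dose-response data and dissects chemokine-receptor recognition from
    atomic structures. The pharmacology arm fits sigmoidal dose-response
    curves to replicated assay panels (G-protein dissociation,
    beta-arrestin recruitment, cAMP, endocytosis), computes
    delta-delta-log(Emax/EC50) bias factors relative to a reference
    ligand, and performs the associated many-vs-one statistical
    comparisons. The structural arm parses PDB/mmCIF coordinates,
    assigns Ballesteros-Weinstein numbering, partitions the
    receptor-chemokine interface into chemokine recognition sites
    (CRS1, CRS1.5, CRS2, CRS3), computes Shrake-Rupley solvent-accessible
    and buried surface areas per site, detects hydrogen bonds, classifies
    the Y7.43 polar-network toggle state, and measures inter-state
    rotation and side-chain sway angles by rigid-body superposition.
    A synthetic-data module generates dose-response panels and toy
    structures with analytically known truths for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-data.R'
    'dose-response.R'
    'bias.R'
    'structure-io.R'
    'geometry.R'
    'numbering.R'
    'sites.R'
    'sasa.R'
    'hbonds.R'
    'run.R'
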