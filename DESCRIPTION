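Package: hierasm
Title: Hierarchical Combinatorial Assembly of Protein Complexes from
    Predicted Pairwise Subunit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles large multi-subunit protein complexes from predicted
    structures of subunit pairs and small subsets, such as those produced by
    AlphaFold-Multimer via ColabFold. The package selects a representative
    structure per subunit by mean plDDT, extracts a library of scored rigid
    transformations between representatives from every interacting pair
    (Kabsch superposition on high-confidence residues, scores derived from
    predicted aligned error), and hierarchically assembles the full complex
    by a combinatorial beam search with steric-clash and chain-connectivity
    filtering, RMSD clustering with copy-correspondence resolution, and an
    optional symmetry reward. Crosslinking-derived distance restraints can
    weight and filter candidate subcomplexes, stoichiometries can be scanned
    against one transformation library, and assembled models are ranked by an
    amino-acid-weighted confidence score. A synthetic-fixture generator
    fabricates toy complexes with controllable noise, plDDT, PAE and decoy
    interactions so the whole pipeline can be exercised without a structure
    predictor.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
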