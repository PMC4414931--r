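Package: pocketrank
Title: Rescoring and Re-Ranking of Predicted Ligand-Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing re-ranker for protein-ligand binding-site
    predictions. Candidate pockets from detection tools such as Fpocket are
    represented by evenly spaced solvent-accessible surface points in a
    short belt around the pocket; each point carries a local
    physico-chemical feature vector built by distance-weighted aggregation
    of atom features, a random forest predicts per-point ligandability, and
    pockets are re-ordered by the sum of squared positive-class
    probabilities. Includes the ligand-centric evaluation protocol
    (D_CA/D_CC criteria, Top-n and Top-(n+2) cutoffs, total coverage),
    PLB-index and volume baseline rankers, and a synthetic structure
    generator for self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
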