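Package: amyloidscreen
Title: Geometric Screening of Protein Structures for Amyloid-Like
    Parallel Beta-Sheet Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein structures as amyloid or amyloid-like from
    C-alpha coordinates alone, using three geometric rules over pairs of
    distinct, approximately parallel beta-sheet chains: near-constant
    inter-chain minimum C-alpha distances (low standard deviation within
    distance bounds), low backbone curvature (mean pseudo-bond angle), and
    a minimum fragment length relative to the chain. Includes PDB/mmCIF
    readers reduced to a C-alpha trace model, a synthetic structure
    generator (cross-beta stacks, helix bundles, beta-barrels) with known
    ground truth, and a batch screening pipeline that emits an amyloid
    list, a fragment table and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
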