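Package: ddgscan
Title: Saturation Stability Scanning of Protein Domains for Missense and
    In-Frame Deletion Variants
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: In silico saturation scanning of protein-domain stability
    (folding free-energy changes, ddG) for both missense substitutions and
    single-residue in-frame deletions. Deletion variants are modelled by
    building seeded ensembles of gap-closed backbone models, relaxing each
    model in independent trajectories, aggregating scores by the median,
    subtracting a percentile baseline and scaling to kcal/mol. Downstream
    tools join ddG tables with allele-frequency and clinical-label tables
    into fishtail and per-segment heatmap classification outputs. A built-in
    deterministic coarse-grained scorer supports desk-scale testing; an
    adapter contract mirrors external all-atom relax/score tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
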