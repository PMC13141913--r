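Package: phagemine
Title: Mining, Quantification and Statistics for Infant Gut Phageomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the computational stages of an infant gut phageome
    study: removal of prophage regions from bacterial reference databases
    ("unphaging") with contig splitting, multi-classifier consensus phage
    calling, greedy dereplication of phage contigs at identity and coverage
    thresholds, post-processing of taxonomy, lifestyle and host predictions,
    viral-relative-unit (VRU) abundance quantification from depth summaries,
    and a statistical layer with Shannon diversity, Pearson-correlation
    distances, principal coordinates analysis, PERMANOVA and linear or
    binomial mixed models with per-infant random intercepts. Includes
    synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    lme4,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
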