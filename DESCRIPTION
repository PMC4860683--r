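Package: admixgeo
Title: Biogeographic Ancestry Inference from Admixture Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the geographic origin of individuals from K-component
    admixture proportion vectors matched against a curated reference panel of
    populations with known coordinates. Provides genetic admixture distances
    and cohort comparisons, leave-one-out assignment accuracy against region
    boundary polygons, iterative reference-panel curation with k-means
    subpopulation splitting, spatial interpolation of admixture signatures
    over geography with simulation of "native" individuals, haplogroup
    frequency statistics for cohort-labelled mtDNA and Y tables, and a
    synthetic-data generator producing spatially structured admixture
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    geosphere,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'curation.R'
    'distance.R'
    'field.R'
    'gps.R'
    'haplogroups.R'
    'io.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
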