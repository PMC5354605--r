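Package: pombescreen
Title: Colony-Array Scoring and Phenotype Quantification for Fission Yeast Genetic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the computational layer of synthetic genetic array
    (SGA) screens in Schizosaccharomyces pombe: quantification of colony
    arrays from plate images on a fixed grid, median normalization of
    colony sizes, query/control ratio scoring and threshold-based
    classification of genetic interactions with replicate intersection,
    plus quantification of three microscopy validation phenotypes (cell
    elongation from area and perimeter, live/dead viability counts, and
    vacuole diameter from ring-stained images) and the associated
    statistics (unpaired t test, one-way ANOVA with Tukey post-test,
    standard error of the mean). A synthetic-data generator produces
    colony arrays and fluorescence cell fields with known ground truth so
    that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
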