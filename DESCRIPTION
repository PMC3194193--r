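Package: kinsaap
Title: Structural Analysis of Pathogenic and Neutral Amino-Acid Substitutions on a Consensus Kinase Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares pathogenic deviations with neutral polymorphisms in a
    protein family by projecting single amino-acid substitutions onto one
    consensus structural model. Provides probe-rolling solvent-accessible
    surface area with a relative-accessibility burial rule, Shannon-entropy
    sequence conservation, rule-based classification of hypothesized
    structural effects of substitutions, the Xd harmonic-deviation statistic
    for proximity of mutation sets to functional feature residues, and
    two-sided Fisher exact enrichment of amino-acid compositions and effect
    categories. Includes a seeded synthetic-data generator (structures,
    alignments, feature sets and mutation classes with planted signal) so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
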