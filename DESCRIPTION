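Package: strchip
Title: STR Profiling and Authentication of Murine Cell Lines from
    Lab-on-Chip Electropherograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fragment length analysis of short-tandem-repeat (STR)
    multiplex PCR products on microfluidic electrophoresis chips, for the
    authentication of primary murine cell lines. Provides a configurable
    ten-marker panel model (nine tetranucleotide murine loci plus one human
    contamination sentinel), a seeded simulator of chip electropherograms
    (ladder wells, sample wells, two-genome mixtures, optional stutter),
    peak detection with ladder calibration and internal-marker alignment,
    size-range based allele calling, and profile comparison for identity
    verification, passage stability and intra-/inter-species
    cross-contamination detection using Tanabe and Masters match scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
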