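Package: tasiphase
Title: Two-Hit tasiRNA Biogenesis Inference from Plant Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers trans-acting siRNA (tasiRNA) biogenesis under the
    two-hit miR390/TAS3 trigger model: discovers and scores miRNA
    complementary sites on candidate TAS transcripts with plant-style
    penalty scoring (G:U wobble, position weighting), decides which site
    is sliced, sets the 21-nt phase from the scissile bond, enumerates
    plus- and minus-strand phase registers, assigns small-RNA reads to
    registers with a phasing enrichment statistic, predicts tasiRNA mRNA
    targets, and maps 5'-end (RLM-RACE/degradome) tags to cleavage
    positions. A synthetic-data module generates TAS-like loci, phased
    read sets, and tag sets with complete ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
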