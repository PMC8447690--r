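Package: tadloop
Title: Differential TADs and Promoter-Distal Looping Genes from Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream comparison of binned Hi-C contact data between two
    culture conditions: LOWESS inter-sample bias normalization of contact
    matrices, eight-type classification of TAD changes between conditions,
    assignment of significant interaction fragments to promoter-distal (P1D1)
    loops, valid-pairs-per-million (VPPM) loop-strength scoring, detection of
    strengthened looping genes, and intersection with differential expression
    to yield differentially expressed looping genes. Includes a synthetic-data
    generator that emits every input dialect with known ground truth, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
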