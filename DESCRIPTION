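Package: sagetag
Title: HT-SuperSAGE Tag Profiling and Gene-Family Expression Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital gene-expression analysis for HT-SuperSAGE libraries:
    extraction and counting of 26-bp NlaIII-anchored tags, per-library
    singleton exclusion and tags-per-million normalisation, pairwise
    differential expression by the Audic-Claverie exact test with signed
    fold changes, anchoring of unitags to EST references under strict
    identity rules, keyword/GO mining of gene families (aquaporin
    PIP/TIP/NIP/SIP subfamilies), and isoform-level reporting. Includes a
    seeded synthetic-data generator emulating four bulked root libraries
    from drought-tolerant and -sensitive sugarcane genotypes so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
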