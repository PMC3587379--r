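Package: promkit
Title: Proximal Promoter Identification and Cis-Regulatory Co-Occurrence Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies mammalian proximal promoter regions with CpG-stratified
    support vector machines that fuse over-represented hexamer counts,
    mono/di/tri-nucleotide composition, and nearest-neighbor DNA duplex
    stability features. Annotates input sequences with CpG islands, GC-content
    and free-energy profiles, MATCH-style position-weight-matrix hits, and
    TATA/CCAAT/GC-box elements, and mines statistically significant
    co-occurring transcription-factor binding sites in gene groups using
    Apriori association rules scored by the hypergeometric distribution.
    Includes a synthetic promoter generator with planted regulatory structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
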