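Package: fegs
Title: Graphical and Statistical Feature Extraction for Alignment-Free
    Protein Sequence Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts protein sequences into fixed-length numerical
    descriptors by fusing cone-based three-dimensional graphical-curve
    features (normalized leading eigenvalues of line/length matrices, one
    per physicochemical property index) with amino-acid and dipeptide
    composition, yielding a 578-dimensional vector per sequence under the
    full 158-property configuration. Includes an AAindex1 flat-file
    parser with missing-value filtering and exact-duplicate removal,
    principal-component reduction, cosine distance, single- and
    complete-linkage tree construction with Newick export, flat
    clustering, and Adjusted Rand Index evaluation against taxonomic
    labels, plus a reproducible synthetic protein-sequence generator for
    testing the pipeline without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
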