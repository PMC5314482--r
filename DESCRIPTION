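Package: datarepo
Title: Data-Centered Management of Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained repository for analysis artifacts with rich
    annotations (descriptions, tags, typed relations, provenance URLs, MD5
    checksums). The data flow of an analysis is reconstructed a posteriori
    from dependency annotations rather than designed up front: items can be
    stored, retrieved, versioned, attached, queried by tag algebra, checked
    for integrity, exchanged between repositories, and rebuilt from
    chunk-annotated source code with recursive, skip-aware dependency
    resolution. Listing and report operations return tibbles; a thin
    command-line interface is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
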