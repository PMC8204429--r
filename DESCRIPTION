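Package: tcrclone
Title: Clonal Analysis of T Cell Receptor Beta Repertoires Across Tissues
    and Memory Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of AIRR-format T cell receptor beta
    rearrangement data: clone assembly with copy-number filters, clonal
    diversity via normalized Shannon entropy, TRBV gene usage matrices,
    replicate-averaged cosine similarity between samples, CDR3
    edit-distance and V-gene Kullback-Leibler divergence hierarchies,
    per-clone tracking across tissue sites, and a synthetic multi-donor,
    multi-tissue repertoire generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
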