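Package: taxmatch
Title: Near ('Fuzzy') Matching of Taxonomic Scientific Names
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconciliation of possibly misspelled organism scientific names
    against a reference checklist using the Taxamatch strategy: a modified
    Damerau-Levenshtein edit distance that recognises transposed
    multi-character blocks, custom phonetic key encoders tuned to latinized
    names (with gender normalization of species epithets), heuristic pre- and
    post-filters that make matching scale to large checklists, result shaping
    and ranking, and a padded n-gram similarity for name authorities.
    Includes a synthetic checklist and misspelling generator with a
    recall/precision/F1 evaluation harness, a naive brute-force reference
    engine for verification, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
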