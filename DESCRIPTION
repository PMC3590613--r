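Package: tcmdx
Title: Ontology-Assisted Syndrome Differentiation from Clinical Case Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a Traditional Chinese Medicine (TCM) diagnostic
    library from three-column clinical case tables (disease, syndrome, symptom
    list) and for ontology-assisted syndrome differentiation. Minimum
    syndrome-to-symptom and disease-to-symptom mappings are extracted with a
    t-threshold adaptive set intersection (galloping search over sorted symptom
    sets); candidate syndromes are refined through a syndrome ontology carrying
    equivalence, inheritance (is-a) and subsume (part-of-union) axioms parsed
    from OWL/RDF-XML or a plain triple dialect; free-text symptom queries are
    matched to library entries with a longest-common-subsequence fuzzy
    similarity and combined into a disease plus syndrome diagnosis. A seeded
    synthetic case generator with planted syndrome signatures supports recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
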