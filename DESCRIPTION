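Package: aopminer
Title: Dictionary-Driven Text Mining of Adverse Outcome Pathway Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts stressor-event and event-event associations from
    literature abstract corpora by dictionary matching with stop-word removal,
    Porter stemming and synonym expansion; scores each co-occurrence link with
    a one-sided Fisher exact test and a four-level confidence scheme; annotates
    biological events against local extracts of toxicological databases
    (AOP-Wiki, KEGG, Reactome, WikiPathways, UniProt, HPA, DISEASES, DisGeNET);
    and assembles the results into filterable, undirected adverse outcome
    pathway networks exported as Cytoscape-compatible JSON and TSV tables.
    Includes a synthetic-corpus generator that plants known co-occurrence
    structure so every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
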