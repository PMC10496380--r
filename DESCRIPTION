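Package: itpnet
Title: Ingredient-Target-Pathway Interaction Networks for Natural-Product
    Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanism-of-action studies of multi-component herbal
    extracts screened by affinity ultrafiltration LC-MS. Covers the annotation
    arithmetic (molecular-formula parsing, monoisotopic mass, protonated-adduct
    m/z, ppm-tolerance matching against a compound library) and the
    sample-versus-control enrichment screen; builds the merged
    ingredient-pathway interaction network and its ingredient-ingredient,
    ingredient-pathway bipartite, and pathway-pathway subnetworks from
    ingredient-to-target and target-to-pathway mapping tables by shared-target
    rules; computes the standard network-statistics suite (degree distribution,
    density, average path length, diameter, clustering coefficient and
    spectrum, degree/betweenness/closeness centralities, log-log power-law
    exponent) and ranks key ingredients and pathways. Includes a seeded
    synthetic-data generator emulating the mapping structure of such studies,
    readers and writers for two-column mapping tables, Pajek .net and GraphML,
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
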