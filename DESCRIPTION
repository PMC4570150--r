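Package: cargomine
Title: Mining Species Interactions and Their Geography from Sequence and
    Citation Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline, file-driven pipeline that extracts species-species
    ("cargo in/on carrier") interactions and species-location interactions
    from nucleotide-sequence metadata (taxon identifier, host and country
    source qualifiers) and from publication-citation co-occurrence.  Includes
    a taxonomy loader with rank reclassification and species roll-up, a
    tiered gazetteer for two-level (country, admin1 region) location
    disambiguation, a staged host-string disambiguator, PubMed-style search
    term generation with PMID-set intersection evidence, exporters for the
    published interaction and location table schemas, dataset-overlap
    validation statistics, a shared-cargo network summary, and a
    deterministic synthetic-fixture generator with ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
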