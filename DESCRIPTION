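Package: oncodomains
Title: Domain-Centric Detection of Somatic Mutation Hotspots in Protein
    Domain Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates somatic tumor variants from all genes sharing a
    protein domain onto aligned domain-family ("oncodomain") positions and
    identifies positions mutated more often than expected under a
    zero-inflated Poisson empirical null, using a local false discovery
    rate computed from a two-component count mixture fitted by
    expectation-maximisation.  Includes parsers for MAF variant tables and
    profile-alignment inputs, projection of protein residues onto domain
    model coordinates, alignment-column entropy conservation scoring,
    Fisher exact enrichment of hotspot positions in functional features
    and annotation terms, a synthetic-cohort generator with planted
    hotspots, cohort subsampling ("bootstrap") experiments, and an
    end-to-end pipeline with TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
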