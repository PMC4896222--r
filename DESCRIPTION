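Package: ssrmine
Title: SSR Association Mapping and Elite Allele Mining in Structured Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-allelic SSR (microsatellite) genotype
    panels from inbred crop accessions: per-locus diversity statistics (allele
    counts, gene diversity, polymorphism information content), Nei distance and
    neighbor-joining phylogeny, admixture-model population structure with
    Evanno delta-K model selection, allele-sharing kinship, multi-allelic
    linkage-disequilibrium D' with permutation significance and log-distance
    decay regression, broad-sense heritability from replicated trials, a Q+K
    mixed-linear-model genome scan with P3D variance components, allele-effect
    estimation against the null-allele reference class, elite-allele mining,
    and allele-pyramiding cross prediction. Includes a seeded generator of
    structured synthetic panels with known QTL architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
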