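Package: holorad
Title: Hologenome Analysis from Type IIB Restriction (2bRAD) Sequencing
Version: 0.1.0
Authors@R: person("holorad", "developers", role = c("aut", "cre"),
    email = "holorad@example.org")
Description: Tools for joint host genotyping and microbiome profiling from a
    single type IIB restriction-site-associated DNA (2bRAD) sequencing
    library. Builds a hologenome database of host-unique and microbial
    taxon-specific restriction tags from reference genomes, quality-filters
    sequencing reads, extracts and partitions tags into host and microbial
    fractions, calls codominant diploid host genotypes with a binomial
    likelihood model, estimates species-level relative abundances with a
    G-score false-positive filter, and computes replicate-agreement,
    alpha/beta diversity, ordination and neighbor-joining tree summaries.
    Includes a fully seeded synthetic holobiome simulator that provides
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    ape,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
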