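Package: sexsatkit
Title: Satellite DNA Catalog Comparison and Sex-Linked Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing satellite DNA (satDNA) repeat content
    between sex-chromosome systems from low-coverage short-read data:
    rotation- and strand-tolerant pairwise identity between satDNA
    consensus monomers with variant/family/superfamily classification;
    read-based genomic abundance and Kimura 2-parameter divergence per
    satDNA, with male:female abundance ratios; extraction of monomer
    haplotypes from reads, singleton filtering, and minimum spanning
    trees over haplotypes in nucleotide mutational steps with per-group
    exclusivity statistics; and screening of SNP genotype matrices for
    perfectly sex-linked loci (XY and ZW patterns) together with the
    number of such loci expected by chance. A synthetic-data module
    generates reads, catalogs, and genotype matrices with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
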