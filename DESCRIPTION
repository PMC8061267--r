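Package: stockscan
Title: Fine-Scale Population Structure and Stocking Introgression from
    RAD-Seq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-genotyping inference chain for resolving fine-scale
    population structure and hatchery-stocking introgression from RAD-seq
    genotypes of freshwater fish. Implements quality filtering (missingness,
    minor-allele count, HDplot paralog detection, F_IS), microhaplotype
    assembly from phased RAD tags, per-population diversity statistics and
    linkage-disequilibrium effective population size, Weir-Cockerham F_ST
    with permutation tests, Nei's D_A neighbour-joining dendrograms with
    bootstrap support, hierarchical AMOVA, Monmonier boundary detection on a
    Delaunay connectivity network, microhaplotype co-ancestry painting with
    group contrasts, supervised ancestry estimation by EM, and a
    Gaussian-kernel smoothed windowed F_ST genome scan with a two-stage
    bootstrap null. A synthetic stocked-metapopulation generator with known
    ground truth exercises every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
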