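Package: snpbarcode
Title: SNP Panels and Sequence Segments as Genetic Barcodes for Cultivar
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forensic-style identity statistics and duplicate detection for
    diploid SNP genotype panels, with LD-aware "super locus" handling and
    sequence-segment genetic barcoding. Implements per-locus selection
    statistics (allele frequencies, observed and expected heterozygosity,
    polymorphic information content, fixation coefficient, exact
    Hardy-Weinberg test, Weir-Cockerham Fst), EM haplotype-frequency
    estimation and LD r2 with permutation significance, multilocus genotype
    matching with missing data, probability-of-identity statistics (PI,
    PIsibs, PIpar-off) and discrimination capacity, haplotype and nucleotide
    diversity of aligned gene segments with EM phasing, neighbour-joining
    trees on Tajima-Nei distances with reference-based hybrid screening,
    and synthetic generators (Balding-Nichols populations, clonal
    collections, segment haplotype pools) that emulate a structured pummelo
    germplasm collection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
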