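Package: ovmx
Title: Variant Mining and Population Genetics for Ovine Mx Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines single-nucleotide variants and short deletions from
    cohort read pileups of the sheep interferon-induced Mx genes (MX1 and
    MX2), annotates their coding consequences (transitions/transversions,
    synonymous, missense, nonsense and frameshift changes with
    translation of the shifted frame to the next stop codon), and
    analyses their population genetics: allele and genotype frequencies,
    Hardy-Weinberg conformance, between-flock allele-frequency
    comparisons, sire genotype inference from progeny under Mendelian
    transmission, haplotype enumeration over linked sites, and relative
    expression from qPCR cycle thresholds. A seedable synthetic-cohort
    generator produces diploid read pileups, pedigrees and closed-flock
    allele trajectories so that every stage of the pipeline can be
    exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
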