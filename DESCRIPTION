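Package: breedscan
Title: Mapping Linked Morphological Variants from Across-Breed GWAS and
    Pooled Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for mapping linked trait loci segregating
    among dog breeds from pooled resequencing and across-breed association
    data. Implements a pooled-pileup SNP caller with tiered fixation
    cutoffs, phenotype-segregation candidate filtering with a
    whole-genome-pool consistency check, dog-wolf fixed-difference
    detection, breed-permutation association testing with genome-wide
    (max-statistic) empirical p-values, EM haplotype phasing with pairwise
    linkage disequilibrium (|D'| and r-squared), a windowed read-depth scan
    for copy-number variation, and a windowed heterozygosity/FST selective
    sweep scan. A synthetic-data generator emulating breed-structured
    sequencing pools with planted causal haplotype blocks makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
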