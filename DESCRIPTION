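Package: qtlperm
Title: Cis-QTL Mapping with Permutation-Based Multiple-Testing Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis quantitative trait loci (QTLs) by scanning, for each
    molecular phenotype, all genetic variants within a window around its
    genomic anchor for the strongest Pearson correlation, and corrects the
    resulting nominal P-value for the many correlated variants tested using
    permutations. Three schemes are provided: a direct scheme with a fixed
    number of permutations, an adaptive scheme that stops early once enough
    stronger null associations have been seen, and a beta approximation in
    which the null distribution of the per-permutation minimum P-value is
    modelled as a Beta(k, n) distribution with shapes fitted by maximum
    likelihood, so that small adjusted P-values can be estimated from a
    modest number of permutations. Genome-wide significance across
    phenotypes is assessed with the Storey-Tibshirani false discovery rate
    procedure. Genotype dosages are read from VCF (plain or bgzip+Tabix),
    phenotypes from UCSC BED, and a synthetic-data generator with planted
    effects and tunable linkage disequilibrium supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
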