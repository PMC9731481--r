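Package: tagsnp
Title: Many-Objective Evolutionary Selection of Tag SNPs in Haplotype Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects tag SNP subsets from a haplotype block (a binary
    matrix of distinct haplotype patterns by biallelic SNPs) by
    many-objective evolutionary search. Four objectives are optimized
    jointly: compactness (number of selected SNPs), tolerance to missing
    data (minimum pairwise distinguish count), dissimilarity (average
    pairwise Hamming distance on the selected SNPs) and balance (variance
    of those distances). Provides NSGA-II, SPEA2, NSGA-III and MOEA/D
    search strategies with random or greedy set-cover initialization, a
    founder/recombination synthetic block generator, Pareto-front quality
    metrics (range, SumMin, MinSum, tolerance rates, average Hamming
    distance, hypervolume) and a command-line interface for generating
    blocks, running selections and benchmarking algorithm grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
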