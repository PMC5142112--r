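Package: backflow
Title: Admixture Inference, Dating and Post-Admixture Genome Analysis with a
    Built-In Wright-Fisher Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting, quantifying and dating gene flow between
    diverged populations, motivated by studies of Holocene Eurasian backflow
    into African genomes. Implements f3/f4/D admixture statistics with
    weighted block-jackknife standard errors, f4-ratio and supervised
    maximum-likelihood ancestry proportions, weighted-LD exponential-decay
    admixture dating (ALDER/MALDER style), the population branch statistic
    (PBS) selection scan with neutral post-admixture allele-frequency
    expectations, PCA-based local-ancestry calling and masking,
    heterozygosity and runs-of-homozygosity summaries by ancestry segment,
    and rho-statistic Y-chromosome node dating on perfect phylogenies.
    A forward-time Wright-Fisher demographic simulator with tracked ancestry
    tracts provides ground-truthed synthetic panels, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    minpack.lm,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
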