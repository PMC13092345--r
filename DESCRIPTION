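Package: flucsel
Title: Simulation and Genomic Footprints of Seasonally Fluctuating Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of a single selected locus
    embedded in a recombining neutral sequence under seasonally fluctuating
    selection, heterozygote advantage, hard and soft selective sweeps, and
    neutrality. Provides windowed population-genetic summary statistics
    (nucleotide diversity, Watterson's theta, Tajima's D, unfolded-SFS
    moments, the NCD balancing-selection statistic with neutral
    standardization, Garud's H haplotype statistics and haplotype spectra),
    pairwise mode comparisons (Welch t-tests with Hochberg correction,
    Cohen's d and distribution overlap), and a stepwise Wilks-lambda linear
    discriminant pipeline with seasonal sampling schemes for classifying
    selection modes from haplotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ape,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
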