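Package: diatomsim
Title: Individual-Based Simulation of Diatom Bloom Microevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time, individual-based neutral simulator of the
    microevolution of bloom-forming planktonic diatoms with a diplontic
    life cycle. Populations of diploid cells carry microsatellite
    genotypes on a single chromosome; they divide clonally on a seasonal
    schedule (fast during month-long blooms, slowly during the stationary
    phase), undergo one partial sexual event per bloom with crossover
    recombination that never breaks a tandem repeat, and are down-sampled
    daily to a time-varying carrying capacity, producing post-bloom
    genetic bottlenecks. The package also provides the population-genetics
    metrics used to monitor such runs (allele and multilocus-genotype
    counts, observed heterozygosity, genotypic diversity), allele
    presence/absence profiles with the binomial deviance dissimilarity,
    PCA and non-metric multidimensional scaling of the resulting
    matrices, detection of the three-stage within-bloom diversity
    signature, and the factorial experiment grid over mutation,
    recombination and sex rates.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
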