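Package: breedsim
Title: Forward-in-Time Simulation of Genetics and Breeding Populations
Version: 0.1.0
Authors@R:
    person("breedsim", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modular forward-in-time simulation platform for population
    and quantitative genetics and for plant and animal breeding programs.
    Provides a generalized genetic-model container (environments, traits,
    linked multi-allelic loci with per-allele mutation-rate matrices, genes,
    epistasis networks, cytoplasm effects and fertility actions), a diploid
    population engine (recombination under Haldane's mapping function,
    nuclear and cytoplasmic mutation, fertility-weighted random mating,
    selfing, doubled haploids), per-individual genotypic and phenotypic
    value calculation, population statistics (allele frequencies, gene
    diversity, additive/dominance variance decomposition, inbreeding
    estimators, mutation-drift equilibrium theory), selection operators,
    and application pipelines for genetic-drift experiments, phenotypic
    recurrent selection, and tester choice in hybrid breeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
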