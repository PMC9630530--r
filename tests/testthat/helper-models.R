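# Fixture models built in code, shared across test files.

# One biallelic additive gene, one environment, one trait.
minimal_model <- function(values = c(0, 0.5, 1), h2 = 0.5, ve = NULL) {
  finalize_gmodel(genetic_model(
    name = "minimal",
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(list(name = "T1", h2 = h2, ve = ve)),
    chromosomes = data.frame(name = "C1", n_loci = 1L),
    loci = data.frame(name = "L1", chrom = 1L, pos_cM = 0, k = 2L,
                      is_gene = TRUE, mutates = FALSE),
    genes = list(list(locus = 1L, traits = 1L, values = values)),
    ranges = list(traits = data.frame(trait = 1L, lowest = min(values),
                                      highest = max(values)))
  ))
}

# Two linked biallelic loci d cM apart on one chromosome (no trait effects).
two_locus_model <- function(d = 10, k = c(2L, 2L), same_chrom = TRUE) {
  finalize_gmodel(genetic_model(
    name = "twolocus",
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(),
    chromosomes = data.frame(name = c("C1", "C2")[1:(2 - same_chrom)],
                             n_loci = NA_integer_),
    loci = data.frame(
      name = c("L1", "L2"),
      chrom = if (same_chrom) c(1L, 1L) else c(1L, 2L),
      pos_cM = if (same_chrom) c(0, d) else c(0, 0),
      k = k, is_gene = FALSE, mutates = FALSE)
  ))
}

# Kitchen-sink model exercising every collection: 2 environments, 2 traits +
# 1 composite, 2 chromosomes, gene + marker + mutating 3-allele locus,
# an epistasis network, 2 cytoplasms with mutation, a cytoplasm action and
# independent + locus fertility actions.
showcase_model <- function() {
  mut3 <- matrix(c(0.0001, 0.0002,
                   0.0003, 0.0004,
                   0.0005, 0.0006), nrow = 3, byrow = TRUE)
  finalize_gmodel(genetic_model(
    name = "showcase",
    environments = data.frame(name = c("E1", "E2"), frequency = c(0.6, 0.4)),
    traits = list(
      list(name = "T1", h2 = c(0.5, 0.4)),
      list(name = "T2", ve = c(1, 2))
    ),
    composites = list(list(name = "T1plusT2", first = 1L,
                           ops = data.frame(op = "+", trait = 2L))),
    chromosomes = data.frame(name = c("C1", "C2"), n_loci = c(2L, 1L)),
    loci = data.frame(
      name = c("LG1", "LM1", "LG2"),
      chrom = c(1L, 1L, 2L),
      pos_cM = c(0, 10, 0),
      k = c(2L, 3L, 2L),
      is_gene = c(TRUE, FALSE, TRUE),
      mutates = c(FALSE, TRUE, FALSE)),
    mutation = list(NULL, mut3, NULL),
    markers = list(list(locus = 2L, scores = c(0, 1, 2, 1, 3, 4))),
    genes = list(
      # gene 1 on LG1: traits (1), envs (2), genotypes (3) -> 6 values
      list(locus = 1L, traits = 1L, values = c(0, 1, 2, 0, 0.5, 1)),
      # gene 2 on LG2: traits (1,2), envs (2), genotypes (3) -> 12 values
      list(locus = 3L, traits = c(1L, 2L),
           values = c(0, 0.2, 0.4, 0, 0.1, 0.2, 1, 1.5, 2, 1, 1.2, 1.4))
    ),
    networks = list(
      list(trait = 1L, env = 1L, loci = c(1L, 3L),
           values = seq(0.1, 0.9, by = 0.1))
    ),
    cytoplasms = list(
      list(name = "cytA", mutates = TRUE, rates = 0.01),
      list(name = "cytB", mutates = FALSE, rates = numeric(0))
    ),
    cyto_actions = list(
      list(cyto = 2L, trait = 1L, env = 1L, loci = integer(0), values = 1.01)
    ),
    fert_actions = list(
      list(cyto = 2L, loci = integer(0), female = 1.0, male = 0.9),
      list(cyto = 0L, loci = 1L, female = c(1, 1, 0.8), male = c(1, 0.9, 0.7))
    ),
    ranges = list(traits = data.frame(trait = c(1L, 2L), lowest = c(0, 0),
                                      highest = c(3, 2)),
                  markers = data.frame(marker = 1L, lowest = 0, highest = 4))
  ))
}

# Population with the listed diploid genotypes at a single-locus model.
combo_pop <- function(model, pairs, counts = NULL, cyto = NULL) {
  combos <- lapply(seq_len(nrow(pairs)), function(i) {
    list(hap1 = pairs[i, 1L], hap2 = pairs[i, 2L],
         count = if (is.null(counts)) 1L else counts[i],
         cyto = if (is.null(cyto)) NULL else cyto[i])
  })
  create_population(model, population_spec(combinations = combos))
}
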