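test_that("gamete recombination matches Haldane closed form", {
  # heterozygote at 2 loci 10 cM apart: recombinant fraction ~ 0.0906
  m <- two_locus_model(d = 10)
  p <- create_population(m, population_spec(
    combinations = list(list(hap1 = c(1, 1), hap2 = c(2, 2)))))
  set.seed(101)
  n <- 1e5
  g <- breedsim:::make_gametes(p, rep(1L, n))
  rec_frac <- mean(g[, 1] != g[, 2])
  r <- haldane(10)
  expect_lt(abs(rec_frac - r), 3 * sqrt(r * (1 - r) / n))
  # unlinked loci on different chromosomes: recombinant fraction 1/2
  mu <- two_locus_model(same_chrom = FALSE)
  pu <- create_population(mu, population_spec(
    combinations = list(list(hap1 = c(1, 1), hap2 = c(2, 2)))))
  gu <- breedsim:::make_gametes(pu, rep(1L, n))
  rec_u <- mean(gu[, 1] != gu[, 2])
  expect_lt(abs(rec_u - 0.5), 3 * sqrt(0.25 / n))
})

test_that("tightly linked loci in a homozygote give only parental gametes", {
  m <- two_locus_model(d = 0)
  p <- create_population(m, population_spec(
    combinations = list(list(hap1 = c(1, 2), hap2 = c(1, 2)))))
  set.seed(3)
  g <- breedsim:::make_gametes(p, rep(1L, 500))
  expect_true(all(g[, 1] == 1L & g[, 2] == 2L))
  # single gamete accessor
  expect_equal(make_gamete(p, 1), c(1L, 2L))
})

test_that("progeny haplotypes are legal parental mosaics when mutation is off", {
  m <- showcase_model()
  m$loci$mutates[] <- FALSE # freeze mutation for the legality check
  m$mutation <- vector("list", 3)
  set.seed(21)
  p <- create_population(m, population_spec(
    allele_freq = list(c(0.5, 0.5), c(0.3, 0.3, 0.4), c(0.2, 0.8)),
    cyto_freq = c(0.5, 0.5)), 30)
  prog <- cross_one_population(p, 60, use_fertility = FALSE)
  for (i in seq_len(prog$size)) {
    fem <- prog$parents[i, 1]
    mal <- prog$parents[i, 2]
    # at every locus each progeny haplotype equals one of the parent's two
    ok_f <- prog$hap1[i, ] == p$hap1[fem, ] | prog$hap1[i, ] == p$hap2[fem, ]
    ok_m <- prog$hap2[i, ] == p$hap1[mal, ] | prog$hap2[i, ] == p$hap2[mal, ]
    expect_true(all(ok_f) && all(ok_m))
    # maternal cytoplasm inheritance
    expect_equal(prog$cyto[i], p$cyto[fem])
  }
})

test_that("mutation follows the per-copy rate matrix", {
  # no rates -> unchanged
  m0 <- drift_model(3, 0)
  set.seed(2)
  p0 <- create_population(m0, population_spec(
    allele_freq = list(c(1 / 3, 1 / 3, 1 / 3))), 100)
  q0 <- mutate_population(p0)
  expect_identical(q0$hap1, p0$hap1)
  # biallelic forward rate 0.02 on a fixed population: ~2000/1e5 copies
  m1 <- finalize_gmodel(genetic_model(
    environments = data.frame(name = "E1", frequency = 1), traits = list(),
    chromosomes = data.frame(name = "C1", n_loci = NA_integer_),
    loci = data.frame(name = "L1", chrom = 1L, pos_cM = 0, k = 2L,
                      is_gene = FALSE, mutates = TRUE),
    mutation = list(matrix(c(0.02, 0.01), 2, 1, byrow = TRUE))))
  n <- 5e4 # 1e5 allele copies
  p1 <- create_population(m1, population_spec(allele_freq = list(c(1, 0))), n)
  set.seed(11)
  q1 <- mutate_population(p1)
  flipped <- sum(q1$hap1 == 2L) + sum(q1$hap2 == 2L)
  expect_lt(abs(flipped - 2000), 3 * sqrt(1e5 * 0.02 * 0.98))
  # 3-allele transition frequencies from allele 1 follow the matrix row
  rates <- c(0.1, 0.2)
  m3 <- finalize_gmodel(genetic_model(
    environments = data.frame(name = "E1", frequency = 1), traits = list(),
    chromosomes = data.frame(name = "C1", n_loci = NA_integer_),
    loci = data.frame(name = "L1", chrom = 1L, pos_cM = 0, k = 3L,
                      is_gene = FALSE, mutates = TRUE),
    mutation = list(matrix(c(rates, 0, 0, 0, 0), 3, 2, byrow = TRUE))))
  p3 <- create_population(m3, population_spec(allele_freq = list(c(1, 0, 0))),
                          n)
  set.seed(12)
  q3 <- mutate_population(p3)
  counts <- tabulate(c(q3$hap1, q3$hap2), 3)
  probs <- c(1 - sum(rates), rates)
  for (a in 1:3)
    expect_lt(abs(counts[a] / 1e5 - probs[a]),
              3 * sqrt(probs[a] * (1 - probs[a]) / 1e5))
})

test_that("cytoplasm mutates by its rate vector", {
  m <- showcase_model() # cytA mutates to cytB at 0.01
  set.seed(31)
  p <- create_population(m, population_spec(
    allele_freq = list(c(0.5, 0.5), c(0.3, 0.3, 0.4), c(0.2, 0.8)),
    cyto_freq = c(1, 0)), 2e4)
  q <- mutate_population(p)
  switched <- sum(q$cyto == 2L)
  expect_lt(abs(switched - 200), 3 * sqrt(2e4 * 0.01 * 0.99))
})

test_that("crossing reproduces Mendelian expectations", {
  m <- minimal_model()
  # monomorphic parents -> monomorphic progeny (no mutation in model)
  mono <- combo_pop(m, rbind(c(1, 1)), counts = 5L)
  prog <- cross_one_population(mono, 20)
  expect_true(all(prog$hap1 == 1L) && all(prog$hap2 == 1L))
  # two distinct homozygous lines -> all F1 identical heterozygotes
  lineA <- combo_pop(m, rbind(c(1, 1)), counts = 3L)
  lineB <- combo_pop(m, rbind(c(2, 2)), counts = 3L)
  set.seed(8)
  f1 <- cross_two_populations(lineA, lineB, 50)
  expect_true(all(f1$hap1 == 1L) && all(f1$hap2 == 2L))
  # F1 selfed -> F2 1:2:1 within 3 SE at 1e4 progeny
  f2 <- cross_one_population(f1, 1e4, use_fertility = FALSE,
                             pairs = cbind(rep(1L, 1e4), rep(1L, 1e4)))
  gi <- genotype_index(2, f2$hap1[, 1], f2$hap2[, 1])
  obs <- tabulate(gi, 3) / 1e4
  exp_p <- c(0.25, 0.5, 0.25)
  for (g in 1:3)
    expect_lt(abs(obs[g] - exp_p[g]),
              3 * sqrt(exp_p[g] * (1 - exp_p[g]) / 1e4))
  expect_error(cross_one_population(subset_population(mono, integer(0)), 5),
               "empty")
})

test_that("fertility weights control gamete sources", {
  # one male-sterile cytoplasm carrier never sires progeny
  m <- showcase_model() # action: cyto 2 -> male fertility 0.9, female 1.0
  # make it fully male-sterile for the test via a by-combination population
  m2 <- m
  m2$fert_actions[[1]]$male <- 0
  p <- create_population(m2, population_spec(combinations = list(
    list(hap1 = c(1, 1, 1), hap2 = c(1, 1, 1), cyto = 2L), # sterile male
    list(hap1 = c(2, 2, 2), hap2 = c(2, 2, 2), cyto = 1L))))
  set.seed(77)
  prog <- cross_one_population(p, 2000)
  expect_true(all(prog$parents[, 2] == 2L))
  # but it can still be a female parent
  expect_gt(sum(prog$parents[, 1] == 1L), 0)
  expect_error(
    {
      m3 <- m2
      m3$fert_actions[[1]]$female <- 0
      m3$fert_actions[[2]]$female <- c(0, 0, 0)
      pz <- create_population(m3, population_spec(combinations = list(
        list(hap1 = c(1, 1, 1), hap2 = c(1, 1, 1), cyto = 2L))))
      cross_one_population(pz, 10)
    },
    "zero")
})

test_that("selfing and doubled haploids behave as designed", {
  m <- two_locus_model(d = 50)
  # DH of a fully homozygous line is that line
  hom <- create_population(m, population_spec(
    combinations = list(list(hap1 = c(1, 2), hap2 = c(1, 2)))))
  dh <- make_dh(hom, 1L, 10L)
  expect_true(all(dh$hap1 == rep(c(1, 2), each = 10)))
  expect_identical(dh$hap1, dh$hap2)
  # DHs of a heterozygote: homozygous everywhere, allele-1 fraction ~ 0.5
  het <- create_population(m, population_spec(
    combinations = list(list(hap1 = c(1, 1), hap2 = c(2, 2)))))
  set.seed(55)
  dhs <- make_dh(het, 1L, 1e4)
  expect_identical(dhs$hap1, dhs$hap2) # heterozygosity exactly 0
  fr <- mean(dhs$hap1[, 1] == 1L)
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 1e4))
  # selfing a double heterozygote segregates at both loci
  set.seed(56)
  s <- self_individual(het, 1L, 2000)
  expect_equal(s$size, 2000L)
  gi <- genotype_index(2, s$hap1[, 1], s$hap2[, 1])
  expect_true(all(tabulate(gi, 3) > 0))
  # self_population keeps families contiguous by parent
  base <- create_population(m, population_spec(
    allele_freq = rep(list(c(0.5, 0.5)), 2)), 4)
  fams <- self_population(base, 5L)
  expect_equal(fams$parents[, 1], rep(1:4, each = 5))
})

test_that("pure drift conserves expected allele frequency", {
  set.seed(13)
  m <- drift_model(2)
  spec <- population_spec(allele_freq = list(c(0.5, 0.5)))
  finals <- replicate(60, {
    pop <- create_population(m, spec, 20)
    for (g in 1:15) pop <- cross_one_population(pop, 20,
                                                use_fertility = FALSE)
    allele_frequencies(pop)[[1]][1]
  })
  # mean of final frequencies within 4 SE of 0.5 (SE from binomial bound)
  se <- sqrt(0.25 / 60) # conservative: var of a frequency <= 0.25
  expect_lt(abs(mean(finals) - 0.5), 4 * se)
})
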