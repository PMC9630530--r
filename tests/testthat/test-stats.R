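test_that("pure-drift inbreeding theory is exact", {
  expect_equal(inbreeding_drift(10, 0), 0)
  expect_equal(inbreeding_drift(50, 70), 1 - 0.99^70)
  expect_equal(inbreeding_drift(50, 70), 0.5052, tolerance = 1e-4)
  # N = 10 "approaches one after 60-70 generations": F(65) ~ 0.96, and the
  # exact first generation with F > 0.99 is 90 (= ceil(log(0.01)/log(0.95)))
  expect_gt(inbreeding_drift(10, 65), 0.95)
  f <- inbreeding_drift(10, 0:120)
  expect_equal(which(f > 0.99)[1] - 1, 90)
  # nonzero base inbreeding propagates linearly in (1 - F0)
  expect_equal(inbreeding_drift(20, 5, F0 = 0.5),
               1 - (1 - inbreeding_drift(20, 5)) * 0.5)
})

test_that("mutation recursion, equilibrium and Ewens agree with theory", {
  # u = 0 reduces to the one-step pure-drift update
  f1 <- inbreeding_drift(30, 1)
  expect_equal(inbreeding_recursion_mutation(30, 0, 0), f1)
  # fixed-point iteration converges to ~1/(1+4Nu) within u
  for (case in list(c(50, 0.0099), c(10, 0.0019), c(50, 0.0198))) {
    N <- case[1]; u <- case[2]
    f <- 0
    for (i in 1:5000) f <- inbreeding_recursion_mutation(N, u, f)
    expect_lt(abs(f - equilibrium_inbreeding(N, u)), u)
    # and the recursion is stationary at its own fixed point
    expect_equal(inbreeding_recursion_mutation(N, u, f), f, tolerance = 1e-6)
  }
  # anchored equilibrium values
  expect_equal(round(equilibrium_inbreeding(50, 0.0099), 4), 0.3356)
  expect_equal(round(equilibrium_inbreeding(10, 0.0019), 4), 0.9294)
  expect_equal(equilibrium_inbreeding(10, 0), 1)
  # Ewens expectation: limits, anchors, monotonicity, bounds
  expect_equal(ewens_expected_alleles(0, 100), 1)
  expect_equal(round(ewens_expected_alleles(1.98, 100), 2), 8.34)
  expect_equal(round(ewens_expected_alleles(3.96, 100), 2), 13.44)
  th <- c(0.01, 0.1, 1, 2, 5)
  ek <- vapply(th, ewens_expected_alleles, 0, n = 100)
  expect_true(all(diff(ek) > 0))
  ns <- c(2, 10, 50, 200)
  ekn <- vapply(ns, function(n) ewens_expected_alleles(2, n), 0)
  expect_true(all(diff(ekn) > 0))
  expect_true(all(ekn >= 1 & ekn <= ns))
})

test_that("heterozygosity-deficit estimator matches hand-computed oracles", {
  # every subpopulation fixed, alleles split across subpops -> F = 1
  p_fixed <- cbind(c(1, 0), c(0, 1))
  r <- inbreeding_observed_heterozygosity(p_fixed)
  expect_equal(r$H_obs, 0)
  expect_equal(r$F, 1)
  # all subpops identical to base -> F = 0
  p_same <- cbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(inbreeding_observed_heterozygosity(p_same)$F, 0,
               tolerance = 1e-12)
  # hand-computed: columns (0.2, 0.8) and (0.6, 0.4)
  p <- cbind(c(0.2, 0.8), c(0.6, 0.4))
  h_obs <- mean(c(1 - (0.04 + 0.64), 1 - (0.36 + 0.16)))
  pbar <- c(0.4, 0.6)
  h_exp <- 1 - sum(pbar^2)
  r <- inbreeding_observed_heterozygosity(p)
  expect_equal(r$H_obs, h_obs)
  expect_equal(r$H_exp, h_exp)
  expect_equal(r$F, (h_exp - h_obs) / h_exp)
  # undefined F flagged, not zero
  expect_true(is.na(inbreeding_observed_heterozygosity(
    cbind(c(1, 0), c(1, 0)))$F))
})

test_that("homozygosity estimator and retained-allele count are exact", {
  expect_equal(inbreeding_homozygosity(cbind(c(1, 0), c(0, 1))), 1)
  k <- 5
  expect_equal(inbreeding_homozygosity(matrix(1 / k, k, 3)), 1 / k)
  # random frequency table vs direct double sum
  set.seed(33)
  p <- matrix(stats::rexp(4 * 6), 4, 6)
  p <- sweep(p, 2, colSums(p), "/")
  direct <- mean(vapply(seq_len(6), function(j) sum(p[, j]^2), 0))
  expect_equal(inbreeding_homozygosity(p), direct)
  # retained alleles
  expect_equal(count_retained_alleles(cbind(c(1, 0), c(0, 1))), 1)
  expect_equal(count_retained_alleles(matrix(0.25, 4, 2)), 4)
  expect_equal(count_retained_alleles(cbind(c(1, 0), c(0.5, 0.5))), 1.5)
})

# HWE population with exact genotype counts at a single biallelic locus.
exact_hwe_pop <- function(model, n, p) {
  n11 <- round(n * p^2)
  n22 <- round(n * (1 - p)^2)
  n12 <- n - n11 - n22
  combo_pop(model, rbind(c(1, 1), c(1, 2), c(2, 2)),
            counts = c(n11, n12, n22))
}

test_that("variance decomposition matches single-locus closed forms", {
  n <- 1e4
  # additive locus, p = 0.5, values (0, a, 2a): Va = a^2/2, Vd = 0
  a <- 0.7
  m_add <- minimal_model(values = c(0, a, 2 * a), h2 = 0.5)
  pop <- exact_hwe_pop(m_add, n, 0.5)
  st <- calc_pstatistics(pop, traits = 1, envs = 1)$traits[["t1.e1"]]
  expect_equal(st$Va, a^2 / 2, tolerance = 1e-3)
  expect_equal(st$Vd, 0, tolerance = 1e-8)
  expect_equal(st$mean, a, tolerance = 1e-3)
  # complete dominance, p = q = 0.5, values (0, 2a, 2a):
  # Va = 2pq(a + d(q-p))^2 = a^2/2, Vd = (2pqd)^2 = a^2/4 -> Vd/Va = 0.5
  m_dom <- minimal_model(values = c(0, 2 * a, 2 * a), h2 = 0.5)
  pop_d <- exact_hwe_pop(m_dom, n, 0.5)
  st_d <- calc_pstatistics(pop_d, traits = 1, envs = 1)$traits[["t1.e1"]]
  expect_equal(st_d$Va, a^2 / 2, tolerance = 1e-3)
  expect_equal(st_d$Vd, a^2 / 4, tolerance = 1e-3)
  expect_equal(st_d$Vd / st_d$Va, 0.5, tolerance = 1e-3)
  # asymmetric frequency p = 0.3 with dominance d = a (values 0, 2a, 2a
  # recoded as -a, d, a around the midpoint): textbook alpha = a + d(q - p)
  p3 <- 0.3
  pop_3 <- exact_hwe_pop(m_dom, 1e4, p3) # allele 1 freq 0.3 -> q = 0.7 for 2
  # here "a" allele is allele 2 with freq 0.7; recompute with p = freq(allele2)
  pfav <- 1 - p3
  alpha <- a + a * ((1 - pfav) - pfav)
  expect_equal(calc_pstatistics(pop_3, 1, 1)$traits[["t1.e1"]]$Va,
               2 * pfav * (1 - pfav) * alpha^2, tolerance = 5e-3)
})

test_that("two-locus additive model decomposes as the sum of per-locus Va", {
  # enumeration oracle: independent loci in exact HWE proportions
  a1 <- 0.4; a2 <- 1.1
  m <- finalize_gmodel(genetic_model(
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(list(name = "T1", h2 = 0.5)),
    chromosomes = data.frame(name = c("C1", "C2"), n_loci = NA_integer_),
    loci = data.frame(name = c("L1", "L2"), chrom = c(1L, 2L), pos_cM = 0,
                      k = 2L, is_gene = TRUE, mutates = FALSE),
    genes = list(list(locus = 1L, traits = 1L, values = c(0, a1, 2 * a1)),
                 list(locus = 2L, traits = 1L, values = c(0, a2, 2 * a2)))))
  # exact joint HWE counts at p = 0.5: multinomial over 9 combinations
  combos <- expand.grid(g1 = 1:3, g2 = 1:3)
  w <- c(1, 2, 1) / 4
  counts <- round(1600 * w[combos$g1] * w[combos$g2])
  pairs1 <- rbind(c(1, 1), c(1, 2), c(2, 2))
  combos_list <- lapply(seq_len(nrow(combos)), function(i)
    list(hap1 = c(pairs1[combos$g1[i], 1], pairs1[combos$g2[i], 1]),
         hap2 = c(pairs1[combos$g1[i], 2], pairs1[combos$g2[i], 2]),
         count = counts[i]))
  pop <- create_population(m, population_spec(combinations = combos_list))
  st <- calc_pstatistics(pop, 1, 1)$traits[["t1.e1"]]
  expect_equal(st$Va, a1^2 / 2 + a2^2 / 2, tolerance = 1e-3)
  expect_equal(st$Vd, 0, tolerance = 1e-8)
  expect_equal(st$Vg, st$Va, tolerance = 1e-3)
})

test_that("population statistics report frequencies, diversity, H2", {
  m <- minimal_model(values = c(0, 0.5, 1), h2 = 0.2)
  # monomorphic population: all diversities and variances 0
  mono <- combo_pop(m, rbind(c(1, 1)), counts = 10L)
  st <- calc_pstatistics(mono, 1, 1, ve = list(t1.e1 = 1))
  expect_equal(st$diversity, 0)
  expect_equal(st$traits[["t1.e1"]]$Va, 0)
  expect_equal(st$traits[["t1.e1"]]$Vd, 0)
  expect_equal(st$traits[["t1.e1"]]$Vg, 0)
  # frozen Ve gives the H2 ratio
  pop <- exact_hwe_pop(m, 1000, 0.5)
  vg <- stats::var(genotypic_values(pop, 1))
  st2 <- calc_pstatistics(pop, 1, 1, ve = list(t1.e1 = 4 * vg))
  expect_equal(st2$traits[["t1.e1"]]$H2, 0.2)
  expect_error(calc_pstatistics(subset_population(pop, integer(0))), "empty")
})
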