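# ---- Fixture model generators ------------------------------------------------

#' Single-locus drift model
#'
#' One multi-allelic locus on one chromosome, optionally with a uniform
#' pairwise mutation-rate matrix (every allele mutates to every other allele
#' at the same rate, so the total rate per copy is `pairwise_rate * (k - 1)`).
#' The model carries no traits: it exists to study allele-frequency dynamics.
#'
#' @param k number of alleles (>= 2).
#' @param pairwise_rate per-generation mutation rate between any ordered
#'   allele pair (0 = no mutation).
#' @return a finalized `genetic_model`.
#' @export
drift_model <- function(k, pairwise_rate = 0) {
  stopifnot(k >= 2)
  mutates <- pairwise_rate > 0
  mut <- if (mutates)
    list(matrix(pairwise_rate, nrow = k, ncol = k - 1L)) else list(NULL)
  m <- genetic_model(
    name = sprintf("drift_k%d_u%g", k, pairwise_rate),
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(),
    chromosomes = data.frame(name = "C1", n_loci = 1L),
    loci = data.frame(name = "L1", chrom = 1L, pos_cM = 0, k = as.integer(k),
                      is_gene = FALSE, mutates = mutates),
    mutation = mut
  )
  finalize_gmodel(m)
}

#' Quantitative-trait models with additive, dominant and epistatic effects
#'
#' Builds the recurrent-selection fixture: `n_genes` unlinked biallelic genes
#' (one per chromosome) controlling a single trait in a single environment
#' with broad-sense heritability `h2`.
#'
#' * `AD0` (pure additive): the two homozygote values at each locus are drawn
#'   Uniform(0, 1) and the heterozygote is exactly midparent.
#' * `AD1` (additive + dominance): all three genotype values are independent
#'   Uniform(0, 1) draws.
#' * `ADE`: as `AD1`, plus `n_genes / 2` two-locus epistasis networks over
#'   disjoint pairs of the gene loci, each with 9 Uniform(0, 1) values.
#'
#' With `mutation = TRUE` every locus mutates with forward rate 0.02
#' (allele 1 to 2) and reverse rate 0.01. The trait range is computed from
#' per-component extremes (sum of per-locus minima/maxima plus network
#' minima/maxima), so the range endpoints of epistatic models need not be
#' jointly attainable.
#'
#' @param kind `"AD0"`, `"AD1"` or `"ADE"`.
#' @param n_genes number of biallelic genes (even, for `ADE` pairing).
#' @param h2 broad-sense heritability of the trait.
#' @param mutation include forward/reverse mutation at all loci.
#' @param forward,reverse mutation rates used when `mutation = TRUE`.
#' @return a finalized `genetic_model`.
#' @export
ad_model <- function(kind = c("AD0", "AD1", "ADE"), n_genes = 10L,
                     h2 = 0.2, mutation = FALSE,
                     forward = 0.02, reverse = 0.01) {
  kind <- match.arg(kind)
  n_genes <- as.integer(n_genes)
  loci <- data.frame(
    name = paste0("G", seq_len(n_genes)),
    chrom = seq_len(n_genes),
    pos_cM = 0,
    k = 2L,
    is_gene = TRUE,
    mutates = mutation
  )
  mut <- if (mutation)
    rep(list(matrix(c(forward, reverse), nrow = 2L, ncol = 1L)),
        n_genes) else vector("list", n_genes)
  genes <- vector("list", n_genes)
  lo <- hi <- 0
  for (l in seq_len(n_genes)) {
    if (kind == "AD0") {
      hom <- stats::runif(2)
      v <- c(hom[1L], mean(hom), hom[2L])
    } else {
      v <- stats::runif(3)
    }
    genes[[l]] <- list(locus = l, traits = 1L, values = v)
    lo <- lo + min(v)
    hi <- hi + max(v)
  }
  networks <- list()
  if (kind == "ADE") {
    pairs <- matrix(seq_len(n_genes), ncol = 2L, byrow = TRUE)
    for (i in seq_len(nrow(pairs))) {
      v <- stats::runif(9)
      networks[[i]] <- list(trait = 1L, env = 1L, loci = pairs[i, ],
                            values = v)
      lo <- lo + min(v)
      hi <- hi + max(v)
    }
  }
  m <- genetic_model(
    name = sprintf("%s_%dgenes", kind, n_genes),
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(list(name = "trait", h2 = h2)),
    chromosomes = data.frame(name = paste0("C", seq_len(n_genes)),
                             n_loci = 1L),
    loci = loci,
    mutation = mut,
    genes = genes,
    networks = networks,
    ranges = list(traits = data.frame(trait = 1L, lowest = lo, highest = hi))
  )
  finalize_gmodel(m)
}

#' Hybrid-breeding model and founder heterotic groups
#'
#' The tester-choice fixture: one trait controlled by `n_chrom *
#' loci_per_chrom` biallelic gene loci, `loci_per_chrom` per chromosome at
#' `spacing_cM` intervals. Per-locus homozygote values are Uniform(0, 1); the
#' heterozygote is midparent plus a dominance deviation `delta * span / 2`
#' with dominance degree `delta ~ Uniform(-1, 1)` (no overdominance), so
#' testers differ in how well testcrosses expose favorable alleles. No
#' mutation; error variance 0 (selection acts on genotypic values).
#'
#' `hybrid_founders()` draws a heterotic group of fully homozygous inbred
#' lines (allele 1 or 2 with equal probability, independently per line and
#' locus). `tester_line()` builds the all-favorable or all-unfavorable
#' homozygote, where the favorable allele at a locus is the one maximizing
#' the homozygote value.
#'
#' @param n_chrom,loci_per_chrom,spacing_cM genome layout.
#' @return `hybrid_model`: a finalized `genetic_model`.
#' @export
hybrid_model <- function(n_chrom = 10L, loci_per_chrom = 10L,
                         spacing_cM = 10) {
  L <- n_chrom * loci_per_chrom
  loci <- data.frame(
    name = paste0("Q", seq_len(L)),
    chrom = rep(seq_len(n_chrom), each = loci_per_chrom),
    pos_cM = rep(spacing_cM * (seq_len(loci_per_chrom) - 1L), n_chrom),
    k = 2L,
    is_gene = TRUE,
    mutates = FALSE
  )
  genes <- vector("list", L)
  lo <- hi <- 0
  for (l in seq_len(L)) {
    hom <- stats::runif(2)
    delta <- stats::runif(1, -1, 1)
    het <- mean(hom) + delta * abs(diff(hom)) / 2
    v <- c(hom[1L], het, hom[2L])
    genes[[l]] <- list(locus = l, traits = 1L, values = v)
    lo <- lo + min(v)
    hi <- hi + max(v)
  }
  m <- genetic_model(
    name = "hybrid",
    environments = data.frame(name = "E1", frequency = 1),
    traits = list(list(name = "yield", h2 = NULL, ve = 0)),
    chromosomes = data.frame(name = paste0("C", seq_len(n_chrom)),
                             n_loci = loci_per_chrom),
    loci = loci,
    genes = genes,
    ranges = list(traits = data.frame(trait = 1L, lowest = lo, highest = hi))
  )
  finalize_gmodel(m)
}

#' @rdname hybrid_model
#' @param model a `hybrid_model()` result.
#' @param n_lines number of inbred lines in the group.
#' @export
hybrid_founders <- function(model, n_lines = 50L) {
  L <- n_loci(model)
  h <- matrix(sample.int(2L, n_lines * L, replace = TRUE), n_lines, L)
  new_population(model, h, h, rep.int(0L, n_lines),
                 matrix(-1L, n_lines, 2L))
}

#' @rdname hybrid_model
#' @param favorable `TRUE` for the all-favorable homozygote, `FALSE` for the
#'   all-unfavorable one.
#' @export
tester_line <- function(model, favorable = TRUE) {
  fav <- favorable_alleles(model)
  al <- if (favorable) fav else 3L - fav
  h <- matrix(al, 1L, n_loci(model))
  new_population(model, h, h, 0L, matrix(-1L, 1L, 2L))
}

# The favorable allele at each biallelic gene locus: the one whose homozygote
# has the larger genotypic value (trait 1, environment 1).
favorable_alleles <- function(model) {
  fav <- rep(1L, n_loci(model))
  for (g in model$genes) {
    fav[g$locus] <- if (g$values[3L] > g$values[1L]) 2L else 1L
  }
  fav
}

#' Write fixture model and population files
#'
#' Generates one of the bundled fixture kinds and writes its genetic-model
#' JSON plus a base-population file to `dir`.
#'
#' @param kind `"drift"`, `"AD0"`, `"AD1"`, `"ADE"` or `"hybrid"`.
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @param N base-population size (drift and AD kinds).
#' @param k allele count (drift kind).
#' @param pairwise_rate pairwise mutation rate (drift kind).
#' @return named list of written paths.
#' @export
generate_fixture <- function(kind = c("drift", "AD0", "AD1", "ADE", "hybrid"),
                             dir, seed = 1L, N = 100L, k = 4L,
                             pairwise_rate = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "drift") {
    model <- drift_model(k, pairwise_rate)
    spec <- population_spec(allele_freq = list(rep(1 / k, k)))
    pop <- create_population(model, spec, N)
  } else if (kind == "hybrid") {
    model <- hybrid_model()
    pop <- hybrid_founders(model)
  } else {
    model <- ad_model(kind)
    spec <- population_spec(
      allele_freq = rep(list(c(0.5, 0.5)), n_loci(model)))
    pop <- create_population(model, spec, N)
  }
  mpath <- file.path(dir, paste0(kind, "_model.json"))
  ppath <- file.path(dir, paste0(kind, "_pop.txt"))
  write_gmodel(model, mpath)
  write_population(pop, ppath)
  list(model = mpath, population = ppath)
}

# ---- Case studies I & II: genetic drift with and without mutation ------------

#' Simulate genetic drift (optionally with neutral mutation)
#'
#' Repeats, for `runs` replicates: create a base population of size `N` with
#' `k` equally frequent alleles at a single locus, then advance `generations`
#' generations of random-union mating via [cross_one_population()] (mutation
#' applied automatically when the model defines it), recording the allele
#' frequencies each generation. Each replicate is one subpopulation of the
#' drift experiment.
#'
#' The summary computes, per generation: the heterozygosity-deficit
#' inbreeding estimator (appropriate for the pure-drift design), the
#' expected-homozygosity estimator (appropriate at mutation-drift
#' equilibrium), the mean number of retained alleles, and the pure-drift
#' theory trajectory `1 - (1 - 1/2N)^t`.
#'
#' @param N population size.
#' @param k initial allele count (equal base frequencies `1/k`).
#' @param pairwise_rate pairwise mutation rate (0 = pure drift).
#' @param generations number of generations of random mating.
#' @param runs number of replicate subpopulations.
#' @param seed RNG seed.
#' @return list with `freq` (array `k x (generations + 1) x runs` of allele
#'   frequencies, generation 0 first) and `summary` (data.frame per
#'   generation with `F_het_deficit`, `F_homozygosity`, `retained`,
#'   `F_theory`), plus the scenario parameters (`u` is the total rate
#'   `pairwise_rate * (k - 1)`).
#' @export
run_drift <- function(N, k, pairwise_rate = 0, generations = 100L,
                      runs = 100L, seed = 1L) {
  set.seed(seed)
  model <- drift_model(k, pairwise_rate)
  spec <- population_spec(allele_freq = list(rep(1 / k, k)))
  freq <- array(0, dim = c(k, generations + 1L, runs))
  for (r in seq_len(runs)) {
    pop <- create_population(model, spec, N)
    freq[, 1L, r] <- allele_frequencies(pop)[[1L]]
    for (g in seq_len(generations)) {
      pop <- cross_one_population(pop, N, use_fertility = FALSE)
      freq[, g + 1L, r] <- allele_frequencies(pop)[[1L]]
    }
  }
  gens <- 0:generations
  summary <- data.frame(
    generation = gens,
    F_het_deficit = vapply(gens, function(g)
      inbreeding_observed_heterozygosity(freq[, g + 1L, , drop = TRUE])$F, 0),
    F_homozygosity = vapply(gens, function(g)
      inbreeding_homozygosity(freq[, g + 1L, , drop = TRUE]), 0),
    retained = vapply(gens, function(g)
      count_retained_alleles(freq[, g + 1L, , drop = TRUE]), 0),
    F_theory = inbreeding_drift(N, gens)
  )
  list(N = N, k = k, pairwise_rate = pairwise_rate,
       u = pairwise_rate * (k - 1), generations = generations, runs = runs,
       seed = seed, freq = freq, summary = summary)
}

# ---- Case study III: phenotypic recurrent selection --------------------------

# Evaluation units of one PRS cycle. Returns the per-candidate criterion and
# the population whose members are recombined after selection: the candidates
# themselves for PS, the family members for family methods (so that half-sib
# selection transmits only the covariance between a family member and its
# family mean, Va/4, as quantitative-genetics theory prescribes).
prs_evaluate <- function(pop, method, family_size, ve) {
  n <- pop$size
  if (method == "PS") {
    pop <- calc_phenotypic_value(pop, 1L, 1L, ve)
    return(list(criterion = phenotypic_values(pop, 1L, 1L), units = pop,
                unit_size = 1L))
  }
  fam <- switch(method,
    S1 = self_population(pop, family_size),
    S2 = {
      s1 <- self_population(pop, 1L) # one random S1 member per candidate
      self_population(s1, family_size)
    },
    HS = {
      fem <- rep(seq_len(n), each = family_size)
      raw <- sample.int(n - 1L, length(fem), replace = TRUE)
      mal <- raw + (raw >= fem) # random mate distinct from the candidate
      cross_one_population(pop, length(fem), use_fertility = FALSE,
                           pairs = cbind(fem, mal))
    },
    stop("unknown PRS method: ", method)
  )
  fam <- calc_phenotypic_value(fam, 1L, 1L, ve)
  p <- phenotypic_values(fam, 1L, 1L)
  # families are contiguous blocks of family_size, candidate-by-candidate
  list(criterion = colMeans(matrix(p, nrow = family_size)), units = fam,
       unit_size = family_size)
}

#' Phenotypic recurrent selection (mass and family selection)
#'
#' Runs cycles of recurrent selection on a single trait. Each cycle the
#' current population of `pop_size` candidates is evaluated by the chosen
#' method — `PS` (own phenotype), `S1` (mean phenotype of a selfed family),
#' `S2` (mean phenotype of a family selfed for two generations, via one
#' random S1 member), or `HS` (mean phenotype of half-sib progeny from random
#' distinct mates) — the best (`top`; forward cycles) or worst (`bottom`;
#' reverse cycles) `n_selected` units are kept and inter-mated by random
#' union to form the next cycle's population. For `PS` the units are the
#' candidates; for the family methods they are the selected families, whose
#' members are pooled and inter-mated (half-sib family selection therefore
#' exploits a quarter of the additive variance, as theory prescribes).
#'
#' Phenotypes use the error variance `Ve = Vg (1 - H2) / H2`. Under the
#' default `ve_policy = "per_cycle"` Vg is the current cycle's genotypic
#' variance, keeping the realized broad-sense heritability at `H2` every
#' cycle; this reproduces pure-line fixation (selection stays effective as
#' variance shrinks, so an additive model fixes completely and reverse
#' selection without mutation finds no variation to act on). With
#' `ve_policy = "fixed"` Ve is derived once from the cycle-0 population and
#' frozen, so realized heritability erodes as the population fixes. The
#' reported response is the population mean genotypic value rescaled to
#' \[0, 1\] by the model's trait range.
#'
#' @param model a genetic model from [ad_model()] (or compatible: biallelic
#'   trait loci, one trait, trait range set).
#' @param method `"PS"`, `"S1"`, `"S2"` or `"HS"`.
#' @param pop_size candidates per cycle.
#' @param n_selected candidates kept per cycle.
#' @param family_size members per evaluation family (family methods).
#' @param cycles_forward,cycles_reverse numbers of upward then downward
#'   selection cycles.
#' @param runs replicate runs.
#' @param ve_policy `"per_cycle"` (default) or `"fixed"`; see Details.
#' @param seed RNG seed.
#' @return list with `adjusted_mean` (run-averaged vector over cycles
#'   0..cycles_forward+cycles_reverse) and `per_run` (matrix cycles x runs),
#'   plus the configuration.
#' @export
run_prs <- function(model, method = c("PS", "S1", "S2", "HS"),
                    pop_size = 100L, n_selected = 20L, family_size = 10L,
                    cycles_forward = 20L, cycles_reverse = 20L,
                    runs = 10L, ve_policy = c("per_cycle", "fixed"),
                    seed = 1L) {
  method <- match.arg(method)
  ve_policy <- match.arg(ve_policy)
  set.seed(seed)
  n_cycles <- cycles_forward + cycles_reverse
  rng <- model$ranges$traits
  lo <- rng$lowest[rng$trait == 1L]
  hi <- rng$highest[rng$trait == 1L]
  h2 <- model$traits[[1L]]$h2[1L]
  spec <- population_spec(allele_freq = rep(list(c(0.5, 0.5)),
                                            n_loci(model)))
  per_run <- matrix(0, n_cycles + 1L, runs)
  for (r in seq_len(runs)) {
    pop <- create_population(model, spec, pop_size)
    ve <- calc_error_variance(pop, 1L, 1L)
    per_run[1L, r] <- adjust_by_range(mean(genotypic_values(pop, 1L)), lo, hi)
    for (cy in seq_len(n_cycles)) {
      mode <- if (cy <= cycles_forward) "top" else "bottom"
      if (ve_policy == "per_cycle") {
        vg <- stats::var(genotypic_values(pop, 1L))
        ve <- vg * (1 - h2) / h2
      }
      ev <- prs_evaluate(pop, method, family_size, ve)
      sel <- selection_indices(ev$criterion, n_selected, mode)
      # pooled members of the selected units
      member_rows <- as.vector(outer(seq_len(ev$unit_size),
                                     (sel - 1L) * ev$unit_size, `+`))
      parents <- subset_population(ev$units, sort(member_rows))
      pop <- cross_one_population(parents, pop_size, use_fertility = FALSE)
      per_run[cy + 1L, r] <- adjust_by_range(mean(genotypic_values(pop, 1L)),
                                             lo, hi)
    }
  }
  list(method = method, pop_size = pop_size, n_selected = n_selected,
       ve_policy = ve_policy,
       family_size = family_size, cycles_forward = cycles_forward,
       cycles_reverse = cycles_reverse, runs = runs, seed = seed,
       adjusted_mean = rowMeans(per_run), per_run = per_run)
}

# ---- Case study IV: tester choice in hybrid breeding -------------------------

# Genotypic values of the cross of every line in A with every line in B
# (both fully homozygous): the F1 genotypes are deterministic.
cross_values <- function(model, hapA, hapB) {
  nA <- nrow(hapA)
  nB <- nrow(hapB)
  h1 <- hapA[rep(seq_len(nA), each = nB), , drop = FALSE]
  h2 <- hapB[rep(seq_len(nB), nA), , drop = FALSE]
  f1 <- new_population(model, h1, h2, rep.int(0L, nA * nB),
                       matrix(-1L, nA * nB, 2L))
  genotypic_values(f1, 1L)
}

#' Hybrid-breeding simulation: choice of tester
#'
#' Simulates a reciprocal-group hybrid program focused on one improved
#' heterotic group. Each run draws a fresh genetic model ([hybrid_model()])
#' and founder groups, shared by all tester arms so arms differ only in the
#' tester. Per cycle and arm: `n_crosses` biparental crosses among the
#' current group-A lines (random distinct pairs), `dh_per_cross` doubled
#' haploids per cross, a first testcross stage keeping `stage1_frac` of the
#' DH lines on testcross genotypic value with the arm's tester, a second
#' stage keeping `stage2_frac` of those, giving the next cycle's group-A
#' lines. Because DHs and testers are fully homozygous and the model has no
#' mutation, each testcross value is the genotypic value of the unique F1.
#'
#' Reported per cycle and arm: the mean testcross value of the retained
#' lines, the mean of all retained-line x group-B single crosses, and the
#' retained lines' mean per-se value.
#'
#' @param n_lines lines per heterotic group.
#' @param n_crosses biparental crosses per cycle.
#' @param dh_per_cross DH lines per cross.
#' @param stage1_frac,stage2_frac selected fractions at the two testcross
#'   stages.
#' @param cycles breeding cycles.
#' @param runs replicate runs (fresh model + founders each).
#' @param testers character vector among `"random"`, `"favorable"`,
#'   `"unfavorable"`; `"random"` may appear twice for two independent random
#'   testers.
#' @param seed RNG seed.
#' @return list with `panels`: array `cycles x 3 x n_testers` (run-averaged
#'   means of testcrosses, single crosses, lines per se) with tester names,
#'   and the configuration.
#' @export
run_hybrid <- function(n_lines = 50L, n_crosses = 100L, dh_per_cross = 100L,
                       stage1_frac = 0.05, stage2_frac = 0.10,
                       cycles = 10L, runs = 5L,
                       testers = c("random", "random", "favorable",
                                   "unfavorable"),
                       seed = 1L) {
  stopifnot(all(testers %in% c("random", "favorable", "unfavorable")))
  set.seed(seed)
  nt <- length(testers)
  panels <- array(0, dim = c(cycles, 3L, nt),
                  dimnames = list(NULL, c("testcross", "single_cross",
                                          "per_se"),
                                  make.unique(testers)))
  n_dh <- n_crosses * dh_per_cross
  n1 <- max(1L, round(stage1_frac * n_dh))
  n2 <- max(1L, round(stage2_frac * n1))
  for (r in seq_len(runs)) {
    model <- hybrid_model()
    groupA0 <- hybrid_founders(model, n_lines)
    groupB <- hybrid_founders(model, n_lines)
    fav <- favorable_alleles(model)
    tester_haps <- lapply(testers, function(tt) {
      switch(tt,
        random = groupB$hap1[sample.int(n_lines, 1L), , drop = FALSE],
        favorable = matrix(fav, 1L),
        unfavorable = matrix(3L - fav, 1L))
    })
    for (ti in seq_len(nt)) {
      th <- tester_haps[[ti]]
      A <- groupA0
      for (cy in seq_len(cycles)) {
        p1 <- sample.int(A$size, n_crosses, replace = TRUE)
        shift <- sample.int(A$size - 1L, n_crosses, replace = TRUE)
        p2 <- 1L + (p1 - 1L + shift) %% A$size # distinct mate
        f1 <- cross_one_population(A, n_crosses, use_fertility = FALSE,
                                   pairs = cbind(p1, p2))
        dh <- make_dh(f1, seq_len(n_crosses), dh_per_cross)
        tc <- testcross_values(model, dh$hap1, th)
        keep1 <- selection_indices(tc, n1, "top")
        keep2 <- keep1[selection_indices(tc[keep1], n2, "top")]
        stopifnot(length(keep1) == n1, length(keep2) == n2)
        A <- subset_population(dh, keep2)
        tc_kept <- tc[keep2]
        sc <- cross_values(model, A$hap1, groupB$hap1)
        panels[cy, "testcross", ti] <- panels[cy, "testcross", ti] +
          mean(tc_kept) / runs
        panels[cy, "single_cross", ti] <- panels[cy, "single_cross", ti] +
          mean(sc) / runs
        panels[cy, "per_se", ti] <- panels[cy, "per_se", ti] +
          mean(genotypic_values(A, 1L)) / runs
      }
    }
  }
  list(panels = panels, testers = testers, n_lines = n_lines,
       n_crosses = n_crosses, dh_per_cross = dh_per_cross,
       stage1_n = n1, stage2_n = n2, cycles = cycles, runs = runs,
       seed = seed)
}

# Testcross genotypic values of homozygous lines against one homozygous
# tester haplotype (1 x L matrix).
testcross_values <- function(model, line_haps, tester_hap) {
  n <- nrow(line_haps)
  h2 <- tester_hap[rep(1L, n), , drop = FALSE]
  f1 <- new_population(model, line_haps, h2, rep.int(0L, n),
                       matrix(-1L, n, 2L))
  genotypic_values(f1, 1L)
}
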