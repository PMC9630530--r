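# ---- Generation advancement --------------------------------------------------
#
# Gametes are formed per chromosome by a fair-coin choice of the starting
# haplotype followed by a Markov chain of switches: at each inter-locus
# interval the active haplotype switches with probability r, the recombination
# fraction with the preceding locus (Haldane, no interference). Because the
# first locus of each chromosome carries r = 0.5, a single switch chain over
# the whole genome reproduces both the within-chromosome linkage and the free
# recombination between chromosomes.

# Draw one gamete from each parent in `par_idx` (with replacement). Returns a
# length(par_idx) x L integer matrix. Vectorized over gametes; the loop runs
# over loci only.
make_gametes <- function(pop, par_idx) {
  L <- n_loci(pop$model)
  n <- length(par_idx)
  r <- pop$model$loci$recfreq
  r[1L] <- 0.5
  # switch indicators, then cumulative XOR along loci -> active haplotype
  state <- integer(n) # 0 = hap1, 1 = hap2; start value set by r[1] = 0.5
  out <- matrix(0L, n, L)
  h1 <- pop$hap1
  h2 <- pop$hap2
  for (l in seq_len(L)) {
    sw <- stats::runif(n) < r[l]
    state <- (state + sw) %% 2L
    a <- h1[cbind(par_idx, l)]
    a2 <- h2[cbind(par_idx, l)]
    out[, l] <- ifelse(state == 0L, a, a2)
  }
  out
}

#' Sample one gamete from an individual
#'
#' Recombination follows Haldane's model: per chromosome the gamete starts
#' from a fair-coin choice of the two parental haplotypes and switches at each
#' inter-locus interval with the locus's recombination fraction; chromosomes
#' recombine freely.
#'
#' @param pop a `population`.
#' @param individual row index of the parent.
#' @return integer vector of allele indices, one per locus.
#' @export
make_gamete <- function(pop, individual) {
  drop(make_gametes(pop, individual))
}

#' Apply one generation of mutation
#'
#' Independently for each allele copy of each individual at each mutating
#' locus, allele i becomes allele j with probability m_ij (the locus's
#' mutation-rate matrix); with probability 1 - sum_j m_ij the copy is
#' unchanged. At most one event per copy per generation (rates are assumed
#' small). Each individual's cytoplasm mutates analogously using the
#' cytoplasm rate vectors. Crossing operations call this automatically on
#' every newly formed population.
#'
#' @param pop a `population`.
#' @return the mutated `population`.
#' @export
mutate_population <- function(pop) {
  model <- pop$model
  n <- pop$size
  if (n == 0L) return(pop)
  pop$hap1 <- mutate_haplotypes(model, pop$hap1)
  pop$hap2 <- mutate_haplotypes(model, pop$hap2)
  nc <- n_cyto(model)
  if (nc > 1L) {
    cur <- pop$cyto
    u <- stats::runif(n)
    new <- cur
    for (i in seq_len(nc)) {
      cy <- model$cytoplasms[[i]]
      if (!isTRUE(cy$mutates) || !length(cy$rates) || !any(cy$rates > 0)) next
      sel <- which(cur == i)
      if (!length(sel)) next
      thr <- cumsum(cy$rates)
      targets <- seq_len(nc)[-i]
      hit <- findInterval(u[sel], thr, left.open = TRUE) + 1L
      mutated <- u[sel] < thr[length(thr)]
      new[sel[mutated]] <- targets[hit[mutated]]
    }
    pop$cyto <- new
  }
  invalidate(pop)
}

# Apply one round of mutation to a haplotype matrix (n x L). Each allele copy
# mutates independently; at most one event per copy.
mutate_haplotypes <- function(model, H) {
  n <- nrow(H)
  if (n == 0L) return(H)
  for (l in which(model$loci$mutates)) {
    mm <- model$mutation[[l]]
    if (is.null(mm)) next
    k <- model$loci$k[l]
    cur <- H[, l]
    u <- stats::runif(n)
    new <- cur
    for (i in seq_len(k)) {
      sel <- which(cur == i)
      if (!length(sel)) next
      rates <- mm[i, ]
      if (!any(rates > 0)) next
      thr <- cumsum(rates)
      targets <- seq_len(k)[-i]
      # u < thr[1] -> first target, thr[1] <= u < thr[2] -> second, ...
      hit <- findInterval(u[sel], thr, left.open = TRUE) + 1L
      mutated <- u[sel] < thr[length(thr)]
      new[sel[mutated]] <- targets[hit[mutated]]
    }
    H[, l] <- new
  }
  H
}

# Sample parent indices proportional to the given fertility weights.
sample_parents <- function(n_parents, n_draws, w = NULL) {
  if (is.null(w)) return(sample.int(n_parents, n_draws, replace = TRUE))
  if (sum(w) <= 0) stop("all fertility weights are zero")
  if (all(w == w[1L])) return(sample.int(n_parents, n_draws, replace = TRUE))
  sample.int(n_parents, n_draws, replace = TRUE, prob = w)
}

#' Random-union mating within one population
#'
#' Produces `n_progeny` offspring by random union of gametes: for each progeny
#' a female and a male gamete source are drawn independently (with
#' replacement, selfing allowed) with probability proportional to each
#' individual's sex-specific fertility (uniform when no fertility actions are
#' defined). The progeny inherits its cytoplasm from the female parent.
#' Mutation is applied to the new population. Parent ids are recorded.
#'
#' @param pop parent `population` (nonempty).
#' @param n_progeny number of offspring.
#' @param use_fertility weight gamete sources by the fertility values from
#'   [calc_fertility()] (computed on demand); default `TRUE`.
#' @param pairs optional 2-column matrix of explicit (female, male) parent
#'   indices, one row per progeny, overriding random union.
#' @return the progeny `population`.
#' @export
cross_one_population <- function(pop, n_progeny, use_fertility = TRUE,
                                 pairs = NULL) {
  stopifnot(inherits(pop, "population"))
  if (pop$size == 0L) stop("cannot cross an empty population")
  if (!is.null(pairs)) {
    stopifnot(ncol(pairs) == 2L, nrow(pairs) == n_progeny)
    fem <- pairs[, 1L]
    mal <- pairs[, 2L]
  } else {
    wf <- wm <- NULL
    if (use_fertility && length(pop$model$fert_actions)) {
      pop <- calc_fertility(pop)
      wf <- pop$values$fert_f
      wm <- pop$values$fert_m
    }
    fem <- sample_parents(pop$size, n_progeny, wf)
    mal <- sample_parents(pop$size, n_progeny, wm)
  }
  g_f <- make_gametes(pop, fem)
  g_m <- make_gametes(pop, mal)
  prog <- new_population(pop$model, g_f, g_m, pop$cyto[fem],
                         cbind(fem, mal, deparse.level = 0))
  mutate_population(prog)
}

#' Crossing between two populations
#'
#' Female gametes come only from `pop_female` (whose cytoplasms the progeny
#' inherit), male gametes only from `pop_male`; fertility weighting and
#' mutation as in [cross_one_population()]. Recorded parent ids refer to row
#' indices within each source population.
#'
#' @param pop_female,pop_male parent populations sharing a genetic model.
#' @param n_progeny number of offspring.
#' @param use_fertility weight gamete sources by fertility; default `TRUE`.
#' @return the progeny `population`.
#' @export
cross_two_populations <- function(pop_female, pop_male, n_progeny,
                                  use_fertility = TRUE) {
  stopifnot(inherits(pop_female, "population"),
            inherits(pop_male, "population"))
  check_same_model(pop_female, pop_male)
  if (pop_female$size == 0L || pop_male$size == 0L)
    stop("cannot cross an empty population")
  wf <- wm <- NULL
  if (use_fertility && length(pop_female$model$fert_actions)) {
    pop_female <- calc_fertility(pop_female)
    pop_male <- calc_fertility(pop_male)
    wf <- pop_female$values$fert_f
    wm <- pop_male$values$fert_m
  }
  fem <- sample_parents(pop_female$size, n_progeny, wf)
  mal <- sample_parents(pop_male$size, n_progeny, wm)
  g_f <- make_gametes(pop_female, fem)
  g_m <- make_gametes(pop_male, mal)
  prog <- new_population(pop_female$model, g_f, g_m, pop_female$cyto[fem],
                         cbind(fem, mal, deparse.level = 0))
  mutate_population(prog)
}

#' Self-pollinate one individual
#'
#' Selfing is the cross of an individual with itself: each progeny unites two
#' independently drawn gametes of the same parent. Mutation is applied.
#'
#' @param pop a `population`.
#' @param individual parent row index.
#' @param n_progeny family size.
#' @return a `population` of selfed progeny.
#' @export
self_individual <- function(pop, individual, n_progeny) {
  pairs <- matrix(individual, n_progeny, 2L)
  cross_one_population(pop, n_progeny, use_fertility = FALSE, pairs = pairs)
}

#' Self-pollinate every individual of a population at once
#'
#' Equivalent to `n_progeny` independent selfed offspring per parent, returned
#' as one population ordered parent-by-parent (parent 1's family first). Used
#' by family-selection pipelines where per-parent [self_individual()] calls
#' would dominate run time.
#'
#' @param pop a `population`.
#' @param n_progeny family size per parent.
#' @return a `population` of `size * n_progeny` selfed progeny.
#' @export
self_population <- function(pop, n_progeny) {
  par <- rep(seq_len(pop$size), each = n_progeny)
  cross_one_population(pop, length(par), use_fertility = FALSE,
                       pairs = cbind(par, par))
}

#' Produce doubled haploids
#'
#' Each doubled haploid (DH) is a single gamete doubled into a fully
#' homozygous diploid; its cytoplasm is the parent's. Mutation is applied to
#' the gamete before doubling, so a DH is homozygous at every locus by
#' construction.
#'
#' @param pop a `population`.
#' @param individual parent row index; or a vector of parent indices, one per
#'   DH, to derive DHs from many parents in one call.
#' @param n_progeny number of DHs per listed parent.
#' @return a `population` of fully homozygous individuals.
#' @export
make_dh <- function(pop, individual, n_progeny = 1L) {
  par <- rep(individual, each = n_progeny)
  g <- make_gametes(pop, par)
  g <- mutate_haplotypes(pop$model, g)
  new_population(pop$model, g, g, pop$cyto[par],
                 cbind(par, par, deparse.level = 0))
}
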