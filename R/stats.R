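# ---- Closed-form population-genetics theory ----------------------------------

#' Inbreeding coefficient under pure drift
#'
#' After t generations of random mating in an idealized population of size N
#' (random union of gametes, selfing allowed, non-overlapping generations):
#' `F_t = 1 - (1 - 1/2N)^t * (1 - F0)`.
#'
#' @param N population size.
#' @param t generation (vectorized).
#' @param F0 inbreeding coefficient of the base population (default 0).
#' @return F_t.
#' @export
#' @examples
#' inbreeding_drift(50, 70) # ~0.505
inbreeding_drift <- function(N, t, F0 = 0) {
  stopifnot(N >= 1, all(t >= 0), F0 >= 0, F0 <= 1)
  1 - (1 - 1 / (2 * N))^t * (1 - F0)
}

#' One-generation inbreeding recursion under neutral mutation
#'
#' `F_t = [1/2N + (1 - 1/2N) F_{t-1}] (1 - u)^2` where u is the total
#' mutation rate per allele copy per generation. With u = 0 this is the
#' one-step update of the pure-drift recursion.
#'
#' @param N population size.
#' @param u total mutation rate.
#' @param F_prev inbreeding coefficient at the previous generation.
#' @return F_t.
#' @export
inbreeding_recursion_mutation <- function(N, u, F_prev) {
  stopifnot(N >= 1, u >= 0, all(F_prev >= 0), all(F_prev <= 1))
  (1 / (2 * N) + (1 - 1 / (2 * N)) * F_prev) * (1 - u)^2
}

#' Equilibrium inbreeding coefficient under mutation-drift balance
#'
#' `F = 1 / (1 + 4 N u)`; the fixed point of
#' [inbreeding_recursion_mutation()] under the approximation
#' `1/(1-u)^2 ~ 1 + 2u`.
#'
#' @param N population size.
#' @param u total mutation rate.
#' @return the equilibrium inbreeding coefficient.
#' @export
#' @examples
#' equilibrium_inbreeding(50, 0.0099) # 0.3356
equilibrium_inbreeding <- function(N, u) {
  stopifnot(N >= 1, all(u >= 0))
  1 / (1 + 4 * N * u)
}

#' Expected number of alleles at mutation-drift equilibrium (Ewens)
#'
#' `E(k) = sum_{i=0}^{n-1} theta / (theta + i)` with `theta = 4 N u` and n
#' the number of sampled gene copies; the i = 0 term is taken as 1 so that
#' E(k) -> 1 as theta -> 0.
#'
#' @param theta scaled mutation rate 4Nu.
#' @param n number of gene copies sampled (2N for a whole population).
#' @return expected number of distinct alleles.
#' @export
#' @examples
#' ewens_expected_alleles(1.98, 100) # 8.34
ewens_expected_alleles <- function(theta, n) {
  stopifnot(theta >= 0, n >= 1)
  if (theta == 0) return(1)
  sum(theta / (theta + 0:(n - 1)))
}

# ---- Inbreeding estimators from subpopulation allele frequencies -------------

check_freq_table <- function(p) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("negative allele frequency")
  if (any(abs(colSums(p) - 1) > 1e-6))
    stop("each subpopulation frequency column must sum to 1")
  p
}

#' Inbreeding estimated from the heterozygosity deficit
#'
#' Given observed allele frequencies p_ij (allele i, subpopulation j) of m
#' subpopulations derived from one base population:
#' `H_obs = mean_j (1 - sum_i p_ij^2)`, `H_exp = 1 - sum_i pbar_i^2` with
#' pbar the across-subpopulation mean frequency, and
#' `F = (H_exp - H_obs) / H_exp`.
#'
#' @param p k x m matrix of allele frequencies; columns sum to 1.
#' @return list with `H_obs`, `H_exp`, `F` (`F` is `NA` when `H_exp` is 0,
#'   where the estimator is undefined).
#' @export
inbreeding_observed_heterozygosity <- function(p) {
  p <- check_freq_table(p)
  h_obs <- mean(1 - colSums(p^2))
  pbar <- rowMeans(p)
  h_exp <- 1 - sum(pbar^2)
  f <- if (h_exp > 0) (h_exp - h_obs) / h_exp else NA_real_
  list(H_obs = h_obs, H_exp = h_exp, F = f)
}

#' Inbreeding estimated from expected homozygosity
#'
#' `F = mean_j sum_i p_ij^2`: the subpopulation-averaged probability that two
#' randomly united gametes carry the same allele. Appropriate at
#' mutation-drift equilibrium, where allele identity rather than the deficit
#' relative to a base population is the natural measure.
#'
#' @param p k x m matrix of allele frequencies; columns sum to 1.
#' @return the estimated inbreeding coefficient.
#' @export
inbreeding_homozygosity <- function(p) {
  p <- check_freq_table(p)
  mean(colSums(p^2))
}

#' Mean number of retained alleles across subpopulations
#'
#' Counts, per subpopulation, the alleles with nonzero frequency, and
#' averages over subpopulations.
#'
#' @param p k x m matrix of allele frequencies.
#' @return mean retained-allele count.
#' @export
count_retained_alleles <- function(p) {
  p <- as.matrix(p)
  mean(colSums(p > 0))
}

# ---- Empirical population statistics -----------------------------------------

#' Allele frequencies at every locus
#'
#' @param pop a `population`.
#' @return list of numeric vectors, one per locus, each of length `k`
#'   summing to 1 (counted over the `2 * size` allele copies).
#' @export
allele_frequencies <- function(pop) {
  k <- pop$model$loci$k
  lapply(seq_len(n_loci(pop$model)), function(l) {
    tabulate(c(pop$hap1[, l], pop$hap2[, l]), nbins = k[l]) / (2 * pop$size)
  })
}

# Additive/dominance decomposition of genotypic values by least squares.
# Additive: joint regression of G on per-locus allele dosages (k-1 dosage
# columns per locus); Va = population variance of the fitted breeding values.
# Dominance: per locus, the genotype-class means of the additive residuals;
# Vd = variance of the summed per-locus dominance deviations.
decompose_variance <- function(pop, G) {
  n <- pop$size
  L <- n_loci(pop$model)
  k <- pop$model$loci$k
  cols <- list()
  locus_of <- integer(0)
  for (l in seq_len(L)) {
    for (a in 2:k[l]) {
      d <- (pop$hap1[, l] == a) + (pop$hap2[, l] == a)
      if (stats::var(d) > 0) {
        cols[[length(cols) + 1L]] <- d
        locus_of <- c(locus_of, l)
      }
    }
  }
  if (!length(cols)) {
    return(list(Va = 0, Vd = 0, breeding_values = rep(mean(G), n)))
  }
  X <- do.call(cbind, cols)
  fit <- stats::lm.fit(cbind(1, X), G)
  bv <- fit$fitted.values
  va <- stats::var(bv)
  # dominance deviations: per locus, class means of the residual by genotype
  res <- G - bv
  dd <- rep(0, n)
  for (l in unique(locus_of)) {
    gi <- genotype_index(k[l], pop$hap1[, l], pop$hap2[, l])
    cls <- tapply(res, gi, mean)
    dd <- dd + as.numeric(cls[as.character(gi)])
  }
  vd <- if (length(unique(locus_of))) stats::var(dd) else 0
  list(Va = va, Vd = vd, breeding_values = bv)
}

#' Population statistics
#'
#' Computes, for each requested trait/environment: the mean and genotypic
#' variance of G, broad-sense heritability `H2 = Vg / (Vg + Ve)` at the given
#' (frozen) error variance, the additive variance Va (variance of breeding
#' values from a joint least-squares regression of G on per-locus allele
#' dosages), the dominance variance Vd (variance of per-locus dominance
#' deviations fit after the additive model), and narrow-sense
#' `h2 = Va / (Vg + Ve)`. Also: per-locus allele frequencies, per-locus gene
#' diversity `1 - sum p^2`, mean diversity, cytoplasm frequencies, marker
#' score mean, and the correlation matrix of genotypic values across the
#' requested trait/environment combinations (when there are at least two).
#'
#' @param pop a `population` (nonempty).
#' @param traits trait indices to summarize (default: all).
#' @param envs environment indices (default: 1).
#' @param ve optional named list / vector of frozen error variances keyed
#'   `"t<trait>.e<env>"`; missing entries are derived from the population
#'   itself via [calc_error_variance()].
#' @return an object of class `pop_stats`.
#' @export
calc_pstatistics <- function(pop, traits = seq_along(pop$model$traits),
                             envs = 1L, ve = NULL) {
  if (pop$size == 0L) stop("cannot compute statistics of an empty population")
  freqs <- allele_frequencies(pop)
  div <- vapply(freqs, function(f) 1 - sum(f^2), 0)
  nc <- n_cyto(pop$model)
  cyto_freq <- if (nc > 0L) tabulate(pop$cyto, nbins = nc) / pop$size else
    numeric(0)

  trait_stats <- list()
  gmat <- NULL
  for (tr in traits) {
    for (e in envs) {
      key <- value_key(tr, e)
      G <- genotypic_values(pop, tr, e)
      gmat <- cbind(gmat, G)
      colnames(gmat)[ncol(gmat)] <- key
      vg <- stats::var(G)
      ve_te <- if (!is.null(ve) && !is.null(ve[[key]])) ve[[key]] else
        tryCatch(calc_error_variance(pop, tr, e), error = function(err) NA_real_)
      dec <- decompose_variance(pop, G)
      h2_broad <- if (!is.na(ve_te) && vg + ve_te > 0) vg / (vg + ve_te) else
        NA_real_
      h2_narrow <- if (!is.na(ve_te) && vg + ve_te > 0)
        dec$Va / (vg + ve_te) else NA_real_
      trait_stats[[key]] <- list(
        trait = tr, env = e, mean = mean(G), Vg = vg, Va = dec$Va,
        Vd = dec$Vd, Ve = ve_te, H2 = h2_broad, h2 = h2_narrow
      )
    }
  }
  trait_cor <- if (!is.null(gmat) && ncol(gmat) >= 2L &&
                   all(apply(gmat, 2, stats::var) > 0))
    stats::cor(gmat) else NULL

  marker_mean <- if (length(pop$model$markers)) {
    mean(calc_marker_scores(pop)$values$marker_score)
  } else NA_real_

  structure(
    list(
      size = pop$size,
      allele_freq = freqs,
      diversity = div,
      mean_diversity = mean(div),
      cyto_freq = cyto_freq,
      traits = trait_stats,
      trait_cor = trait_cor,
      marker_score_mean = marker_mean
    ),
    class = "pop_stats"
  )
}

#' @export
print.pop_stats <- function(x, ...) {
  cat("<pop_stats> n = ", x$size,
      " | mean gene diversity = ", signif(x$mean_diversity, 4), "\n", sep = "")
  for (key in names(x$traits)) {
    ts <- x$traits[[key]]
    cat(sprintf("  %s: mean %.4g  Vg %.4g  Va %.4g  Vd %.4g  H2 %.3g\n",
                key, ts$mean, ts$Vg, ts$Va, ts$Vd, ts$H2))
  }
  invisible(x)
}
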