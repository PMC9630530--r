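# ---- Selection operators -----------------------------------------------------

#' Randomly select individuals
#'
#' Uniform sample of `n` individuals without replacement.
#'
#' @param pop a `population`.
#' @param n number to select (`0 <= n <= size`).
#' @return a `population` of the selected individuals.
#' @export
select_random <- function(pop, n) {
  if (n > pop$size) stop("cannot select ", n, " from ", pop$size)
  if (n == 0L) return(subset_population(pop, integer(0)))
  subset_population(pop, sample.int(pop$size, n))
}

# Rank-based index choice shared by individual- and family-level selection.
# Ties are broken by original index (stable), so runs are seed-reproducible.
selection_indices <- function(values, n,
                              mode = c("top", "bottom", "middle", "random")) {
  mode <- match.arg(mode)
  m <- length(values)
  if (n > m) stop("cannot select ", n, " from ", m)
  if (anyNA(values)) stop("selection criterion contains missing values")
  if (n == 0L) return(integer(0))
  if (mode == "random") return(sample.int(m, n))
  ord <- order(values, seq_len(m)) # ascending, stable
  switch(mode,
    top = sort(order(-values, seq_len(m))[seq_len(n)]),
    bottom = sort(ord[seq_len(n)]),
    middle = {
      # contiguous rank window centered on the median rank ceil((m+1)/2)
      center <- ceiling((m + 1) / 2)
      lo <- center - ceiling((n - 1) / 2)
      lo <- max(1L, min(lo, m - n + 1L))
      sort(ord[lo:(lo + n - 1L)])
    }
  )
}

#' Select individuals by a criterion value
#'
#' Truncation selection on any per-individual criterion: `top` keeps the `n`
#' largest values, `bottom` the `n` smallest, `middle` a contiguous rank
#' window centered on the median rank, and `random` ignores the values. Ties
#' are broken by original index so results are reproducible. The output
#' preserves the original individual order.
#'
#' @param pop a `population`.
#' @param values numeric criterion, one value per individual (e.g. phenotypes
#'   from [phenotypic_values()], genotypic values, or marker scores).
#' @param n number of individuals to keep.
#' @param mode `"top"`, `"bottom"`, `"middle"`, or `"random"`.
#' @return a `population` of the selected individuals.
#' @export
select_individuals <- function(pop, values, n,
                               mode = c("top", "bottom", "middle", "random")) {
  if (length(values) != pop$size)
    stop("criterion length ", length(values), " != population size ", pop$size)
  subset_population(pop, selection_indices(values, n, mode))
}

#' Among-family selection
#'
#' Families are ranked by the mean of their members' criterion values and
#' selected with the same modes as [select_individuals()]. Ties are broken by
#' family index.
#'
#' @param families list of `population`s (the families; all nonempty).
#' @param values list of numeric vectors, criterion values per family member,
#'   parallel to `families`.
#' @param n number of families to keep.
#' @param mode selection mode.
#' @return list with `families` (the selected populations) and `indices`
#'   (their positions in the input list).
#' @export
select_among_families <- function(families, values, n,
                                  mode = c("top", "bottom", "middle",
                                           "random")) {
  if (length(families) != length(values))
    stop("families and values must be parallel lists")
  if (any(vapply(families, function(f) f$size, 0L) == 0L))
    stop("empty family")
  means <- vapply(values, mean, 0)
  idx <- selection_indices(means, n, mode)
  list(families = families[idx], indices = idx, means = means)
}
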