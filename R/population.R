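# ---- Population container ----------------------------------------------------
#
# A population stores its diploid genotypes as two integer matrices (one per
# homologous chromosome set), size x n_loci, phased. Rows are individuals in a
# fixed order; all structural operations preserve that order. The population
# carries a reference to its genetic model so that downstream operations never
# need the model passed separately, and cross-model operations can be refused.

new_population <- function(model, hap1, hap2, cyto, parents,
                           mode = "by_combination") {
  structure(
    list(
      model = model,
      size = nrow(hap1),
      mode = mode,
      hap1 = hap1,
      hap2 = hap2,
      cyto = cyto,
      parents = parents,
      values = NULL,
      stats = NULL
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat("<population> size ", x$size, " | model '", x$model$name,
      "' (", n_loci(x$model), " loci) | mode ", x$mode, "\n", sep = "")
  invisible(x)
}

check_same_model <- function(a, b) {
  if (!identical(a$model$name, b$model$name) ||
      !identical(a$model$loci$k, b$model$loci$k))
    stop("populations belong to different genetic models")
}

# any structural change invalidates cached values/statistics
invalidate <- function(pop) {
  pop$values <- NULL
  pop$stats <- NULL
  pop
}

#' Specify how founder genotypes are generated
#'
#' Either per-locus allele-frequency vectors (founders drawn in Hardy-Weinberg
#' and linkage equilibrium) or a list of explicit allele combinations with
#' counts.
#'
#' @param allele_freq list of numeric vectors, one per locus, each of length
#'   `k` and summing to 1.
#' @param cyto_freq numeric vector of cytoplasm frequencies (ignored when the
#'   model has no cytoplasms).
#' @param combinations list of lists with fields `hap1`, `hap2` (allele-index
#'   vectors over loci), optional `cyto` (default 1) and `count` (default 1).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(allele_freq = NULL, cyto_freq = NULL,
                            combinations = NULL) {
  if (is.null(allele_freq) == is.null(combinations))
    stop("give exactly one of allele_freq or combinations")
  if (!is.null(allele_freq)) {
    for (f in allele_freq)
      if (abs(sum(f) - 1) > 1e-9)
        stop("allele frequencies must sum to 1")
    if (!is.null(cyto_freq) && abs(sum(cyto_freq) - 1) > 1e-9)
      stop("cytoplasm frequencies must sum to 1")
    structure(list(mode = "by_frequency", allele_freq = allele_freq,
                   cyto_freq = cyto_freq), class = "population_spec")
  } else {
    structure(list(mode = "by_combination", combinations = combinations),
              class = "population_spec")
  }
}

#' Create a founder population
#'
#' Under `by_frequency`, each of the `2 * size` allele copies at each locus is
#' drawn i.i.d. from the locus allele-frequency vector, so founders are in
#' Hardy-Weinberg and linkage equilibrium; cytoplasms are drawn from the
#' cytoplasm frequencies. Under `by_combination`, individuals are instantiated
#' exactly as listed. Founders get parent ids (-1, -1).
#'
#' @param model a finalized `genetic_model`.
#' @param spec a [population_spec()].
#' @param size number of individuals (ignored under `by_combination`, where
#'   the counts in the spec determine the size).
#' @return a `population`.
#' @export
create_population <- function(model, spec, size = NULL) {
  stopifnot(inherits(model, "genetic_model"), inherits(spec, "population_spec"))
  L <- n_loci(model)
  k <- model$loci$k
  if (spec$mode == "by_frequency") {
    stopifnot(!is.null(size), size >= 0)
    if (length(spec$allele_freq) != L)
      stop("spec has ", length(spec$allele_freq), " frequency vectors for ",
           L, " loci")
    hap1 <- matrix(0L, size, L)
    hap2 <- matrix(0L, size, L)
    for (l in seq_len(L)) {
      f <- spec$allele_freq[[l]]
      if (length(f) != k[l])
        stop("locus ", l, ": frequency vector length ", length(f),
             " != allele count ", k[l])
      hap1[, l] <- sample.int(k[l], size, replace = TRUE, prob = f)
      hap2[, l] <- sample.int(k[l], size, replace = TRUE, prob = f)
    }
    nc <- n_cyto(model)
    cyto <- if (nc > 0L) {
      cf <- spec$cyto_freq
      if (is.null(cf)) cf <- rep(1 / nc, nc)
      sample.int(nc, size, replace = TRUE, prob = cf)
    } else rep.int(0L, size)
    parents <- matrix(-1L, size, 2L)
    new_population(model, hap1, hap2, cyto, parents, mode = "by_frequency")
  } else {
    combos <- spec$combinations
    counts <- vapply(combos, function(cb)
      if (is.null(cb$count)) 1L else as.integer(cb$count), 0L)
    n <- sum(counts)
    hap1 <- matrix(0L, n, L)
    hap2 <- matrix(0L, n, L)
    cyto <- integer(n)
    row <- 1L
    for (ci in seq_along(combos)) {
      cb <- combos[[ci]]
      if (length(cb$hap1) != L || length(cb$hap2) != L)
        stop("combination ", ci, ": haplotype length != number of loci")
      if (any(cb$hap1 > k) || any(cb$hap2 > k) ||
          any(cb$hap1 < 1L) || any(cb$hap2 < 1L))
        stop("combination ", ci, ": allele index out of model range")
      rows <- row:(row + counts[ci] - 1L)
      hap1[rows, ] <- matrix(as.integer(cb$hap1), counts[ci], L, byrow = TRUE)
      hap2[rows, ] <- matrix(as.integer(cb$hap2), counts[ci], L, byrow = TRUE)
      cyto[rows] <- if (is.null(cb$cyto)) min(1L, n_cyto(model)) else
        as.integer(cb$cyto)
      row <- row + counts[ci]
    }
    parents <- matrix(-1L, n, 2L)
    new_population(model, hap1, hap2, cyto, parents, mode = "by_combination")
  }
}

# ---- serialization -----------------------------------------------------------

#' Read / write a population file
#'
#' Plain-text format: a header with the model name, size and definition mode,
#' then one record per individual: the two parent ids, the cytoplasm index,
#' and one phased `i/j` allele pair per locus in model locus order.
#'
#' @param model the `genetic_model` the population belongs to.
#' @param path file path.
#' @return `read_population`: a `population`; `write_population`: `path`,
#'   invisibly.
#' @export
read_population <- function(model, path) {
  if (!file.exists(path)) stop("population file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(lines[1L], "\\s+")[[1L]]
  if (length(hdr) < 3L) stop("malformed population header")
  size <- as.integer(hdr[2L])
  mode <- hdr[3L]
  L <- n_loci(model)
  k <- model$loci$k
  recs <- lines[-1L]
  if (length(recs) != size)
    stop("header declares ", size, " individuals, file has ", length(recs))
  hap1 <- matrix(0L, size, L)
  hap2 <- matrix(0L, size, L)
  cyto <- integer(size)
  parents <- matrix(0L, size, 2L)
  for (i in seq_len(size)) {
    f <- strsplit(recs[i], "\\s+")[[1L]]
    if (length(f) != 3L + L)
      stop("record ", i, ": expected ", 3L + L, " fields, got ", length(f))
    parents[i, ] <- as.integer(f[1:2])
    cyto[i] <- as.integer(f[3L])
    pairs <- strsplit(f[-(1:3)], "/", fixed = TRUE)
    a1 <- as.integer(vapply(pairs, `[`, "", 1L))
    a2 <- as.integer(vapply(pairs, `[`, "", 2L))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop("record ", i, ": malformed allele pair")
    bad <- which(a1 > k | a2 > k | a1 < 1L | a2 < 1L)
    if (length(bad))
      stop("record ", i, ": allele out of range at locus ", bad[1L],
           " (k = ", k[bad[1L]], ")")
    hap1[i, ] <- a1
    hap2[i, ] <- a2
  }
  new_population(model, hap1, hap2, cyto, parents, mode = mode)
}

#' @rdname read_population
#' @param pop a `population`.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  hdr <- paste(pop$model$name, pop$size, pop$mode)
  recs <- vapply(seq_len(pop$size), function(i) {
    paste(pop$parents[i, 1L], pop$parents[i, 2L], pop$cyto[i],
          paste(pop$hap1[i, ], pop$hap2[i, ], sep = "/", collapse = " "))
  }, "")
  writeLines(c("# breedsim population", hdr, recs), path)
  invisible(path)
}

# ---- structural operations ---------------------------------------------------

#' Merge, split and combine populations
#'
#' `merge_populations(a, b)` concatenates two populations of the same model
#' (individuals of `a` first). `merge_many(pops)` folds a list of populations
#' the same way. `split_population(pop)` returns a list of size-1 populations,
#' one per individual, so `merge_many(split_population(p))` restores `p`'s
#' individuals in order. Cached values and statistics are dropped because they
#' no longer describe the result.
#'
#' @param a,b populations sharing a genetic model.
#' @return a `population`, or a list of them for `split_population`.
#' @export
merge_populations <- function(a, b) {
  stopifnot(inherits(a, "population"), inherits(b, "population"))
  check_same_model(a, b)
  out <- new_population(
    a$model,
    rbind(a$hap1, b$hap1),
    rbind(a$hap2, b$hap2),
    c(a$cyto, b$cyto),
    rbind(a$parents, b$parents),
    mode = a$mode
  )
  out
}

#' @rdname merge_populations
#' @param pops list of populations sharing a genetic model.
#' @export
merge_many <- function(pops) {
  stopifnot(length(pops) >= 1L)
  out <- pops[[1L]]
  for (p in pops[-1L]) out <- merge_populations(out, p)
  out
}

#' @rdname merge_populations
#' @param pop a `population`.
#' @export
split_population <- function(pop) {
  lapply(seq_len(pop$size), function(i) subset_population(pop, i))
}

#' Extract a subset of individuals
#'
#' @param pop a `population`.
#' @param idx integer vector of row indices (may repeat; order defines the
#'   output order).
#' @return a `population` with `length(idx)` individuals.
#' @export
subset_population <- function(pop, idx) {
  stopifnot(all(idx >= 1L), all(idx <= pop$size))
  new_population(
    pop$model,
    pop$hap1[idx, , drop = FALSE],
    pop$hap2[idx, , drop = FALSE],
    pop$cyto[idx],
    pop$parents[idx, , drop = FALSE],
    mode = pop$mode
  )
}

#' Export per-individual values as a data.frame / CSV
#'
#' One row per individual: parent ids, cytoplasm, and any computed value
#' columns (fertilities, marker score, genotypic and phenotypic values per
#' trait/environment key).
#'
#' @param pop a `population`.
#' @param path optional CSV output path.
#' @return the data.frame, invisibly when `path` is given.
#' @export
population_values <- function(pop, path = NULL) {
  df <- data.frame(
    id = seq_len(pop$size),
    parent1 = pop$parents[, 1L],
    parent2 = pop$parents[, 2L],
    cytoplasm = pop$cyto
  )
  v <- pop$values
  if (!is.null(v)) {
    if (!is.null(v$fert_f)) {
      df$female_fertility <- v$fert_f
      df$male_fertility <- v$fert_m
    }
    if (!is.null(v$marker_score)) df$marker_score <- v$marker_score
    for (key in names(v$G)) df[[paste0("G_", key)]] <- v$G[[key]]
    for (key in names(v$P)) df[[paste0("P_", key)]] <- v$P[[key]]
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
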