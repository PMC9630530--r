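# ---- genotype indexing -------------------------------------------------------

#' Number of unordered diploid genotypes at a k-allele locus
#'
#' @param k integer vector of allele counts (each >= 1).
#' @return integer vector, `k*(k+1)/2`.
#' @export
#' @examples
#' n_genotypes(c(2, 3, 4)) # 3, 6, 10
n_genotypes <- function(k) {
  as.integer(k * (k + 1L) / 2L)
}

#' Canonical index of an unordered diploid genotype
#'
#' Genotypes at a `k`-allele locus are ordered lexicographically as unordered
#' allele pairs: (1,1), (1,2), ..., (1,k), (2,2), ..., (k,k). The index is
#' 1-based, matching the order in which genotypic-value arrays are stored.
#'
#' @param k allele count at the locus.
#' @param a1,a2 allele indices (1-based); vectors are recycled. Order of the
#'   two alleles is irrelevant.
#' @return integer vector of genotype indices in `1:n_genotypes(k)`.
#' @export
#' @examples
#' genotype_index(2, c(1, 1, 2), c(1, 2, 2)) # 1, 2, 3
genotype_index <- function(k, a1, a2) {
  if (any(a1 < 1L | a1 > k | a2 < 1L | a2 > k))
    stop("allele index out of range 1..", k)
  i <- pmin(a1, a2)
  j <- pmax(a1, a2)
  as.integer((i - 1L) * (2L * k - i + 2L) / 2L + (j - i) + 1L)
}

#' Canonical index of a multi-locus genotype combination
#'
#' Combines per-locus genotype indices into a single row-major rank over the
#' loci in the order given: the *last* locus varies fastest. This is the order
#' in which epistasis-network, cytoplasm-action and fertility-action value
#' arrays are stored.
#'
#' @param ks integer vector of allele counts, one per locus.
#' @param gidx matrix (n x length(ks)) of per-locus genotype indices, or a
#'   vector for a single combination.
#' @return integer vector of combined indices in `1:prod(n_genotypes(ks))`.
#' @export
combo_index <- function(ks, gidx) {
  if (is.vector(gidx)) gidx <- matrix(gidx, nrow = 1L)
  ng <- n_genotypes(ks)
  if (ncol(gidx) != length(ks))
    stop("genotype-index matrix has ", ncol(gidx), " columns for ",
         length(ks), " loci")
  idx <- rep.int(0L, nrow(gidx))
  for (l in seq_along(ks)) {
    idx <- idx * ng[l] + (gidx[, l] - 1L)
  }
  as.integer(idx + 1L)
}

# ---- Haldane mapping function ------------------------------------------------

#' Haldane's mapping function and its inverse
#'
#' Converts a map distance in centiMorgans to a recombination fraction
#' assuming no crossover interference: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d map distance in cM (nonnegative).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
#' @examples
#' haldane(10) # 0.09063
haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane
#' @param r recombination fraction in `[0, 0.5)`.
#' @export
haldane_inv <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

# ---- constructor -------------------------------------------------------------

#' Construct a generalized genetic model
#'
#' The model is the single source of truth for a simulation: environments and
#' their frequencies in the target population of environments (TPE), traits
#' with per-environment heritability and/or error variance, a linkage map of
#' multi-allelic loci (genes or markers) with optional per-allele mutation-rate
#' matrices, genotype-to-value maps for genes, epistasis networks, cytoplasm
#' types with maternal inheritance and optional mutation, cytoplasm actions
#' (independent or interacting with nuclear loci), fertility actions
#' (multiplicative female/male fertility factors), and trait/marker ranges used
#' to rescale values to \[0, 1\].
#'
#' Value arrays are flat vectors in canonical genotype order (see
#' [genotype_index()] and [combo_index()]). Gene values are indexed
#' \[trait, environment, genotype\] with genotype fastest.
#'
#' @param name model name.
#' @param environments data.frame with columns `name`, `frequency`.
#' @param traits list of lists with fields `name`, and per-environment numeric
#'   vectors `h2` and/or `ve` (either may be `NULL`/`NA` where the other is
#'   given).
#' @param chromosomes data.frame with columns `name` and optionally `n_loci`
#'   (checked against the locus table when supplied).
#' @param loci data.frame with columns `name`, `chrom` (chromosome index),
#'   `pos_cM`, `k` (allele count), `is_gene` (logical), `mutates` (logical),
#'   and optionally `recfreq` (recombination fraction with the preceding
#'   locus; `NA` = derive from cM via Haldane).
#' @param mutation list (one element per locus) of `k x (k-1)` rate matrices
#'   (`NULL` for non-mutating loci); row i holds rates from allele i to the
#'   other alleles in ascending allele order.
#' @param markers list of lists with fields `locus`, `scores`
#'   (length `n_genotypes(k)`).
#' @param genes list of lists with fields `locus`, `traits` (trait indices),
#'   `values` (flat, length `n_traits * n_env * n_genotypes(k)`, indexed
#'   \[trait, env, genotype\], genotype fastest).
#' @param networks list of lists with fields `trait`, `env`, `loci` (>= 2
#'   locus indices), `values` (flat, canonical multi-locus order).
#' @param composites list of lists with fields `name`, `first` (trait index)
#'   and `ops` (data.frame with columns `op` in `+ - * /` and `trait`).
#' @param cytoplasms list of lists with fields `name`, `mutates`, `rates`
#'   (length `n_cytoplasms - 1`, rates to the other cytoplasms in ascending
#'   index order).
#' @param cyto_actions list of lists with fields `cyto`, `trait`, `env`,
#'   `loci` (possibly empty), `values`.
#' @param fert_actions list of lists with fields `cyto` (0 = none), `loci`
#'   (possibly empty), `female`, `male` (value arrays).
#' @param ranges list with data.frames `traits` (`trait`, `lowest`, `highest`)
#'   and `markers` (`marker`, `lowest`, `highest`); may be `NULL`.
#' @return an object of class `genetic_model` (not yet finalized; see
#'   [finalize_gmodel()]).
#' @seealso [read_gmodel()], [write_gmodel()], [finalize_gmodel()]
#' @export
genetic_model <- function(name = "model",
                          environments,
                          traits,
                          chromosomes,
                          loci,
                          mutation = NULL,
                          markers = list(),
                          genes = list(),
                          networks = list(),
                          composites = list(),
                          cytoplasms = list(),
                          cyto_actions = list(),
                          fert_actions = list(),
                          ranges = NULL) {
  environments <- as.data.frame(environments)
  chromosomes <- as.data.frame(chromosomes)
  loci <- as.data.frame(loci)
  if (is.null(loci$recfreq)) loci$recfreq <- NA_real_
  loci <- loci[, c("name", "chrom", "pos_cM", "recfreq", "k", "is_gene",
                   "mutates")]
  traits <- lapply(traits, function(tr)
    list(name = tr$name, h2 = tr$h2, ve = tr$ve))
  if (is.null(mutation)) mutation <- vector("list", nrow(loci))
  m <- structure(
    list(
      name = name,
      env = environments,
      traits = traits,
      composites = composites,
      chrom = chromosomes,
      loci = loci,
      mutation = mutation,
      markers = markers,
      genes = genes,
      networks = networks,
      cytoplasms = cytoplasms,
      cyto_actions = cyto_actions,
      fert_actions = fert_actions,
      ranges = ranges,
      finalized = FALSE
    ),
    class = "genetic_model"
  )
  m
}

#' @export
print.genetic_model <- function(x, ...) {
  cat("<genetic_model> ", x$name, "\n", sep = "")
  cat("  environments: ", nrow(x$env),
      " | traits: ", length(x$traits),
      " (+", length(x$composites), " composite)",
      " | chromosomes: ", nrow(x$chrom),
      " | loci: ", nrow(x$loci),
      " (", sum(x$loci$is_gene), " genes, ",
      sum(!x$loci$is_gene), " markers)\n", sep = "")
  cat("  epistasis networks: ", length(x$networks),
      " | cytoplasms: ", length(x$cytoplasms),
      " | cytoplasm actions: ", length(x$cyto_actions),
      " | fertility actions: ", length(x$fert_actions), "\n", sep = "")
  invisible(x)
}

n_env <- function(model) nrow(model$env)
n_loci <- function(model) nrow(model$loci)
n_cyto <- function(model) length(model$cytoplasms)

#' Fill in derived model quantities
#'
#' Computes everything a raw model leaves implicit: recombination fractions
#' with the preceding locus from cM gaps via Haldane's function (the first
#' locus of each chromosome gets r = 0.5, i.e. free recombination with the
#' previous chromosome; an explicitly supplied `recfreq` is kept), per-locus
#' genotype counts, and validates every structural invariant.
#'
#' @param model a `genetic_model`.
#' @return the finalized, validated model.
#' @export
finalize_gmodel <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  loci <- model$loci
  L <- nrow(loci)
  for (ci in unique(loci$chrom)) {
    pos <- loci$pos_cM[loci$chrom == ci]
    if (length(pos) > 1L && is.unsorted(pos))
      stop("loci on chromosome ", ci, " are not sorted by position")
  }
  rec <- loci$recfreq
  for (l in seq_len(L)) {
    if (!is.na(rec[l])) next
    if (l == 1L || loci$chrom[l] != loci$chrom[l - 1L]) {
      rec[l] <- 0.5
    } else {
      d <- loci$pos_cM[l] - loci$pos_cM[l - 1L]
      rec[l] <- haldane(d)
    }
  }
  loci$recfreq <- rec
  loci$n_geno <- n_genotypes(loci$k)
  model$loci <- loci
  counts <- vapply(seq_len(nrow(model$chrom)), function(ci)
    sum(loci$chrom == ci), 0L)
  declared <- model$chrom$n_loci
  if (!is.null(declared)) {
    bad <- which(!is.na(declared) & declared != counts)
    if (length(bad))
      stop("chromosome ", bad[1L], " declares ", declared[bad[1L]],
           " loci but ", counts[bad[1L]], " are assigned to it")
  }
  model$chrom$n_loci <- counts
  model$finalized <- TRUE
  validate_gmodel(model)
  model
}

#' Validate a genetic model
#'
#' Checks all structural invariants: environment frequencies sum to 1, loci
#' sorted by position within chromosome, chromosome locus counts, mutation
#' matrix shapes and row sums < 1, genes only on gene loci and markers only on
#' marker loci, value-array lengths equal to the product of per-locus genotype
#' counts, cytoplasm rate lengths, composite-trait references, and range
#' ordering. Errors name the violated invariant.
#'
#' @param model a `genetic_model`.
#' @return the model, invisibly.
#' @export
validate_gmodel <- function(model) {
  env <- model$env
  if (nrow(env) < 1L) stop("model must define at least one environment")
  if (abs(sum(env$frequency) - 1) > 1e-9)
    stop("environment frequencies must sum to 1 (got ", sum(env$frequency), ")")
  ne <- nrow(env)

  for (ti in seq_along(model$traits)) {
    tr <- model$traits[[ti]]
    h2 <- tr$h2
    ve <- tr$ve
    for (e in seq_len(ne)) {
      h <- if (is.null(h2)) NA_real_ else h2[e]
      v <- if (is.null(ve)) NA_real_ else ve[e]
      if (is.na(h) && is.na(v))
        stop("trait ", tr$name, ": neither heritability nor error variance ",
             "given for environment ", e)
      if (!is.na(h) && (h <= 0 || h > 1))
        stop("trait ", tr$name, ": heritability must be in (0,1]")
      if (!is.na(v) && v < 0)
        stop("trait ", tr$name, ": error variance must be nonnegative")
    }
  }

  loci <- model$loci
  L <- nrow(loci)
  if (any(loci$k < 2L)) stop("every locus needs at least 2 alleles")
  for (ci in seq_len(nrow(model$chrom))) {
    on_chr <- which(loci$chrom == ci)
    if (!is.null(model$chrom$n_loci) && !is.na(model$chrom$n_loci[ci]) &&
        model$chrom$n_loci[ci] != length(on_chr))
      stop("chromosome ", ci, " declares ", model$chrom$n_loci[ci],
           " loci but ", length(on_chr), " are assigned to it")
    if (length(on_chr) > 1L && is.unsorted(loci$pos_cM[on_chr]))
      stop("loci on chromosome ", ci, " are not sorted by position")
  }
  if (length(model$mutation) != L)
    stop("mutation list length must equal number of loci")
  for (l in seq_len(L)) {
    if (!loci$mutates[l]) next
    mm <- model$mutation[[l]]
    k <- loci$k[l]
    if (is.null(mm) || !is.matrix(mm) || any(dim(mm) != c(k, k - 1L)))
      stop("locus ", l, ": mutation matrix must be ", k, " x ", k - 1L)
    if (any(mm < 0)) stop("locus ", l, ": negative mutation rate")
    if (any(rowSums(mm) >= 1))
      stop("locus ", l, ": mutation-rate row sums must be < 1")
  }

  for (mi in seq_along(model$markers)) {
    mk <- model$markers[[mi]]
    if (loci$is_gene[mk$locus])
      stop("marker ", mi, " sits on a gene locus (", mk$locus, ")")
    if (length(mk$scores) != n_genotypes(loci$k[mk$locus]))
      stop("marker ", mi, ": expected ", n_genotypes(loci$k[mk$locus]),
           " genotype scores, got ", length(mk$scores))
  }
  for (gi in seq_along(model$genes)) {
    g <- model$genes[[gi]]
    if (!loci$is_gene[g$locus])
      stop("gene ", gi, " sits on a marker locus (", g$locus, ")")
    want <- length(g$traits) * ne * n_genotypes(loci$k[g$locus])
    if (length(g$values) != want)
      stop("gene ", gi, ": expected ", want, " values, got ",
           length(g$values))
    if (any(g$traits < 1L | g$traits > length(model$traits)))
      stop("gene ", gi, ": trait reference out of range")
  }
  for (ni in seq_along(model$networks)) {
    nw <- model$networks[[ni]]
    if (length(nw$loci) < 2L)
      stop("epistasis network ", ni, " needs at least 2 loci")
    want <- prod(n_genotypes(loci$k[nw$loci]))
    if (length(nw$values) != want)
      stop("network ", ni, ": expected ", want, " values, got ",
           length(nw$values))
  }

  nc <- length(model$cytoplasms)
  for (ci in seq_along(model$cytoplasms)) {
    cy <- model$cytoplasms[[ci]]
    if (isTRUE(cy$mutates)) {
      if (length(cy$rates) != nc - 1L)
        stop("cytoplasm ", ci, ": expected ", nc - 1L, " mutation rates")
      if (sum(cy$rates) >= 1) stop("cytoplasm ", ci, ": rate sum must be < 1")
    }
  }
  for (ai in seq_along(model$cyto_actions)) {
    ca <- model$cyto_actions[[ai]]
    want <- if (length(ca$loci)) prod(n_genotypes(loci$k[ca$loci])) else 1L
    if (length(ca$values) != want)
      stop("cytoplasm action ", ai, ": expected ", want, " values, got ",
           length(ca$values))
    if (ca$cyto < 1L || ca$cyto > nc)
      stop("cytoplasm action ", ai, ": cytoplasm reference out of range")
  }
  for (fi in seq_along(model$fert_actions)) {
    fa <- model$fert_actions[[fi]]
    want <- if (length(fa$loci)) prod(n_genotypes(loci$k[fa$loci])) else 1L
    if (length(fa$female) != want || length(fa$male) != want)
      stop("fertility action ", fi, ": expected ", want,
           " female and male values")
    if (any(fa$female < 0) || any(fa$male < 0))
      stop("fertility action ", fi, ": fertility factors must be >= 0")
  }

  for (ci in seq_along(model$composites)) {
    cp <- model$composites[[ci]]
    refs <- c(cp$first, cp$ops$trait)
    if (any(refs < 1L | refs > length(model$traits)))
      stop("composite trait ", cp$name, ": underlying trait out of range")
    if (any(!cp$ops$op %in% c("+", "-", "*", "/")))
      stop("composite trait ", cp$name, ": operator must be one of + - * /")
  }

  if (!is.null(model$ranges) && !is.null(model$ranges$traits)) {
    rt <- model$ranges$traits
    if (any(rt$lowest > rt$highest))
      stop("trait range: lowest exceeds highest")
  }
  invisible(model)
}

# ---- serialization -----------------------------------------------------------

#' Read a genetic model from a JSON file
#'
#' The file mirrors the model structure with top-level keys `status`,
#' `environments`, `traits`, `composite_traits`, `chromosomes`, `loci`,
#' `markers`, `genes`, `networks`, `cytoplasms`, `cytoplasm_actions`,
#' `fertility_actions`, `ranges`. All indices are 1-based, value arrays flat
#' in canonical genotype order, mutation matrices given row by row (rates from
#' each allele to the others in ascending allele order). The returned model is
#' finalized and validated.
#'
#' @param path path to a JSON model file.
#' @return a finalized `genetic_model`.
#' @export
read_gmodel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  j <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  num <- function(x) as.numeric(unlist(x))
  int <- function(x) as.integer(unlist(x))

  env <- data.frame(
    name = vapply(j$environments, function(e) e$name, ""),
    frequency = vapply(j$environments, function(e) as.numeric(e$frequency), 0)
  )
  traits <- lapply(j$traits, function(tr) {
    list(
      name = tr$name,
      h2 = if (is.null(tr$h2)) NULL else num(tr$h2),
      ve = if (is.null(tr$ve)) NULL else num(tr$ve)
    )
  })
  composites <- lapply(j$composite_traits, function(cp) {
    list(
      name = cp$name,
      first = as.integer(cp$first),
      ops = data.frame(
        op = vapply(cp$ops, function(o) o$op, ""),
        trait = vapply(cp$ops, function(o) as.integer(o$trait), 0L)
      )
    )
  })
  chrom <- data.frame(
    name = vapply(j$chromosomes, function(ch) ch$name, ""),
    n_loci = vapply(j$chromosomes, function(ch)
      if (is.null(ch$n_loci)) NA_integer_ else as.integer(ch$n_loci), 0L)
  )
  loci <- data.frame(
    name = vapply(j$loci, function(l) l$name, ""),
    chrom = vapply(j$loci, function(l) as.integer(l$chrom), 0L),
    pos_cM = vapply(j$loci, function(l) as.numeric(l$pos_cM), 0),
    recfreq = vapply(j$loci, function(l)
      if (is.null(l$recfreq)) NA_real_ else as.numeric(l$recfreq), 0),
    k = vapply(j$loci, function(l) as.integer(l$k), 0L),
    is_gene = vapply(j$loci, function(l) isTRUE(l$is_gene), TRUE),
    mutates = vapply(j$loci, function(l) isTRUE(l$mutates), TRUE)
  )
  mutation <- lapply(j$loci, function(l) {
    if (is.null(l$mutation)) return(NULL)
    k <- as.integer(l$k)
    matrix(num(l$mutation), nrow = k, ncol = k - 1L, byrow = TRUE)
  })
  markers <- lapply(j$markers, function(mk)
    list(locus = as.integer(mk$locus), scores = num(mk$scores)))
  genes <- lapply(j$genes, function(g)
    list(locus = as.integer(g$locus), traits = int(g$traits),
         values = num(g$values)))
  networks <- lapply(j$networks, function(nw)
    list(trait = as.integer(nw$trait), env = as.integer(nw$env),
         loci = int(nw$loci), values = num(nw$values)))
  cytoplasms <- lapply(j$cytoplasms, function(cy)
    list(name = cy$name, mutates = isTRUE(cy$mutates),
         rates = if (is.null(cy$rates)) numeric(0) else num(cy$rates)))
  cyto_actions <- lapply(j$cytoplasm_actions, function(ca)
    list(cyto = as.integer(ca$cyto), trait = as.integer(ca$trait),
         env = as.integer(ca$env),
         loci = if (is.null(ca$loci)) integer(0) else int(ca$loci),
         values = num(ca$values)))
  fert_actions <- lapply(j$fertility_actions, function(fa)
    list(cyto = if (is.null(fa$cyto)) 0L else as.integer(fa$cyto),
         loci = if (is.null(fa$loci)) integer(0) else int(fa$loci),
         female = num(fa$female), male = num(fa$male)))
  ranges <- NULL
  if (!is.null(j$ranges)) {
    ranges <- list()
    if (!is.null(j$ranges$traits))
      ranges$traits <- data.frame(
        trait = vapply(j$ranges$traits, function(r) as.integer(r$trait), 0L),
        lowest = vapply(j$ranges$traits, function(r) as.numeric(r$lowest), 0),
        highest = vapply(j$ranges$traits, function(r) as.numeric(r$highest), 0)
      )
    if (!is.null(j$ranges$markers))
      ranges$markers <- data.frame(
        marker = vapply(j$ranges$markers, function(r) as.integer(r$marker), 0L),
        lowest = vapply(j$ranges$markers, function(r) as.numeric(r$lowest), 0),
        highest = vapply(j$ranges$markers, function(r) as.numeric(r$highest), 0)
      )
  }
  m <- genetic_model(
    name = if (is.null(j$status$name)) "model" else j$status$name,
    environments = env, traits = traits, chromosomes = chrom, loci = loci,
    mutation = mutation, markers = markers, genes = genes,
    networks = networks, composites = composites, cytoplasms = cytoplasms,
    cyto_actions = cyto_actions, fert_actions = fert_actions, ranges = ranges
  )
  finalize_gmodel(m)
}

#' Write a genetic model to a JSON file
#'
#' Inverse of [read_gmodel()]: `read_gmodel(write_gmodel(m, f))` returns a
#' model equal to `m` (up to finalization of derived fields). Empty
#' collections (e.g. no cytoplasms) are omitted from the file.
#'
#' @param model a `genetic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmodel <- function(model, path) {
  stopifnot(inherits(model, "genetic_model"))
  loci <- model$loci
  j <- list(status = list(name = model$name))
  j$environments <- lapply(seq_len(nrow(model$env)), function(i)
    list(name = model$env$name[i], frequency = model$env$frequency[i]))
  j$traits <- lapply(model$traits, function(tr) {
    out <- list(name = tr$name)
    if (!is.null(tr$h2)) out$h2 <- tr$h2
    if (!is.null(tr$ve)) out$ve <- tr$ve
    out
  })
  if (length(model$composites))
    j$composite_traits <- lapply(model$composites, function(cp)
      list(name = cp$name, first = cp$first,
           ops = lapply(seq_len(nrow(cp$ops)), function(i)
             list(op = cp$ops$op[i], trait = cp$ops$trait[i]))))
  j$chromosomes <- lapply(seq_len(nrow(model$chrom)), function(i)
    list(name = model$chrom$name[i],
         n_loci = sum(loci$chrom == i)))
  j$loci <- lapply(seq_len(nrow(loci)), function(l) {
    out <- list(name = loci$name[l], chrom = loci$chrom[l],
                pos_cM = loci$pos_cM[l], k = loci$k[l],
                is_gene = loci$is_gene[l], mutates = loci$mutates[l])
    if (!is.na(loci$recfreq[l])) out$recfreq <- loci$recfreq[l]
    if (!is.null(model$mutation[[l]]))
      out$mutation <- as.vector(t(model$mutation[[l]]))
    out
  })
  if (length(model$markers))
    j$markers <- lapply(model$markers, function(mk)
      list(locus = mk$locus, scores = mk$scores))
  if (length(model$genes))
    j$genes <- lapply(model$genes, function(g)
      list(locus = g$locus, traits = g$traits, values = g$values))
  if (length(model$networks))
    j$networks <- lapply(model$networks, function(nw)
      list(trait = nw$trait, env = nw$env, loci = nw$loci,
           values = nw$values))
  if (length(model$cytoplasms))
    j$cytoplasms <- lapply(model$cytoplasms, function(cy) {
      out <- list(name = cy$name, mutates = isTRUE(cy$mutates))
      if (length(cy$rates)) out$rates <- cy$rates
      out
    })
  if (length(model$cyto_actions))
    j$cytoplasm_actions <- lapply(model$cyto_actions, function(ca)
      list(cyto = ca$cyto, trait = ca$trait, env = ca$env,
           loci = ca$loci, values = ca$values))
  if (length(model$fert_actions))
    j$fertility_actions <- lapply(model$fert_actions, function(fa) {
      out <- list(loci = fa$loci, female = fa$female, male = fa$male)
      if (fa$cyto > 0L) out$cyto <- fa$cyto
      out
    })
  if (!is.null(model$ranges)) {
    rg <- list()
    if (!is.null(model$ranges$traits))
      rg$traits <- lapply(seq_len(nrow(model$ranges$traits)), function(i)
        list(trait = model$ranges$traits$trait[i],
             lowest = model$ranges$traits$lowest[i],
             highest = model$ranges$traits$highest[i]))
    if (!is.null(model$ranges$markers))
      rg$markers <- lapply(seq_len(nrow(model$ranges$markers)), function(i)
        list(marker = model$ranges$markers$marker[i],
             lowest = model$ranges$markers$lowest[i],
             highest = model$ranges$markers$highest[i]))
    j$ranges <- rg
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
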