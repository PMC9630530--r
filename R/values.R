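# ---- Per-individual value computation ----------------------------------------

# Per-locus genotype index for every individual, for the given loci.
# Returns an n x length(loci) integer matrix.
geno_index_matrix <- function(pop, loci) {
  k <- pop$model$loci$k
  out <- matrix(0L, pop$size, length(loci))
  for (j in seq_along(loci)) {
    l <- loci[j]
    out[, j] <- genotype_index(k[l], pop$hap1[, l], pop$hap2[, l])
  }
  out
}

ensure_values <- function(pop) {
  if (is.null(pop$values))
    pop$values <- list(G = list(), P = list())
  pop
}

value_key <- function(trait, env) paste0("t", trait, ".e", env)

#' Compute female and male fertility for every individual
#'
#' Each individual's sex-specific fertility is the product over all fertility
#' actions of the action's value at the individual's multi-locus genotype
#' index. An action tied to a cytoplasm applies only to carriers of that
#' cytoplasm (non-carriers contribute a neutral factor 1); an action with no
#' loci is a single cytoplasm-determined factor. With no actions at all,
#' every fertility is 1.
#'
#' @param pop a `population`.
#' @return the population with `values$fert_f` and `values$fert_m` filled.
#' @export
calc_fertility <- function(pop) {
  pop <- ensure_values(pop)
  if (!is.null(pop$values$fert_f)) return(pop)
  n <- pop$size
  ff <- rep(1, n)
  fm <- rep(1, n)
  for (fa in pop$model$fert_actions) {
    applies <- if (fa$cyto > 0L) pop$cyto == fa$cyto else rep(TRUE, n)
    if (!any(applies)) next
    if (length(fa$loci)) {
      gi <- geno_index_matrix(pop, fa$loci)
      idx <- combo_index(pop$model$loci$k[fa$loci], gi)
      ff[applies] <- ff[applies] * fa$female[idx[applies]]
      fm[applies] <- fm[applies] * fa$male[idx[applies]]
    } else {
      ff[applies] <- ff[applies] * fa$female[1L]
      fm[applies] <- fm[applies] * fa$male[1L]
    }
  }
  pop$values$fert_f <- ff
  pop$values$fert_m <- fm
  pop
}

#' Compute marker scores
#'
#' The marker score of an individual is the sum over all markers of the
#' genotype score at the marker locus; 0 when the model defines no markers.
#'
#' @param pop a `population`.
#' @return the population with `values$marker_score` filled.
#' @export
calc_marker_scores <- function(pop) {
  pop <- ensure_values(pop)
  sc <- rep(0, pop$size)
  for (mk in pop$model$markers) {
    gi <- geno_index_matrix(pop, mk$locus)[, 1L]
    sc <- sc + mk$scores[gi]
  }
  pop$values$marker_score <- sc
  pop
}

#' Compute genotypic values for a trait in an environment
#'
#' G is the sum of three deterministic components: over the trait's genes,
#' the gene value at \[trait, environment, genotype\]; over the trait's
#' epistasis networks matching the environment, the network value at the
#' multi-locus genotype combination; and over matching cytoplasm actions, the
#' action value (carriers of the action's cytoplasm only).
#'
#' @param pop a `population`.
#' @param trait trait index.
#' @param env environment index (default 1).
#' @return the population with `values$G[[key]]` filled (key `"t<trait>.e<env>"`).
#' @export
calc_genotypic_value <- function(pop, trait, env = 1L) {
  model <- pop$model
  if (trait < 1L || trait > length(model$traits))
    stop("trait index out of range")
  if (env < 1L || env > n_env(model))
    stop("environment index out of range")
  pop <- ensure_values(pop)
  key <- value_key(trait, env)
  n <- pop$size
  G <- rep(0, n)
  ne <- n_env(model)
  for (g in model$genes) {
    t_pos <- match(trait, g$traits)
    if (is.na(t_pos)) next
    ng <- n_genotypes(model$loci$k[g$locus])
    # flat order [trait, env, genotype], genotype fastest
    offset <- ((t_pos - 1L) * ne + (env - 1L)) * ng
    gi <- geno_index_matrix(pop, g$locus)[, 1L]
    G <- G + g$values[offset + gi]
  }
  for (nw in model$networks) {
    if (nw$trait != trait || nw$env != env) next
    gi <- geno_index_matrix(pop, nw$loci)
    idx <- combo_index(model$loci$k[nw$loci], gi)
    G <- G + nw$values[idx]
  }
  for (ca in model$cyto_actions) {
    if (ca$trait != trait || ca$env != env) next
    carriers <- pop$cyto == ca$cyto
    if (!any(carriers)) next
    if (length(ca$loci)) {
      gi <- geno_index_matrix(pop, ca$loci)
      idx <- combo_index(model$loci$k[ca$loci], gi)
      G[carriers] <- G[carriers] + ca$values[idx[carriers]]
    } else {
      G[carriers] <- G[carriers] + ca$values[1L]
    }
  }
  pop$values$G[[key]] <- G
  pop
}

#' Genotypic / phenotypic values as plain vectors
#'
#' Accessors for the per-individual value blocks; values are computed on
#' demand if missing (phenotypes cannot be computed on demand because they
#' need an error variance — see [calc_phenotypic_value()]).
#'
#' @param pop a `population`.
#' @param trait trait index.
#' @param env environment index.
#' @return numeric vector of length `pop$size`.
#' @export
genotypic_values <- function(pop, trait, env = 1L) {
  key <- value_key(trait, env)
  if (is.null(pop$values$G[[key]]))
    pop <- calc_genotypic_value(pop, trait, env)
  pop$values$G[[key]]
}

#' @rdname genotypic_values
#' @export
phenotypic_values <- function(pop, trait, env = 1L) {
  key <- value_key(trait, env)
  p <- pop$values$P[[key]]
  if (is.null(p)) stop("phenotypes not computed; call calc_phenotypic_value()")
  p
}

#' Error variance for a trait in an environment
#'
#' Returns the trait's stored error variance when the model gives one.
#' Otherwise it is derived from the broad-sense heritability and the
#' genotypic variance of a reference population:
#' `Ve = Vg * (1 - H2) / H2`. By convention the reference is the experiment's
#' initial (cycle-0) population and the derived Ve is held fixed afterwards,
#' so selection changes realized heritability but not the error scale.
#'
#' @param pop_ref reference `population` (used only when Ve is derived).
#' @param trait trait index.
#' @param env environment index.
#' @return the error variance (scalar).
#' @export
calc_error_variance <- function(pop_ref, trait, env = 1L) {
  tr <- pop_ref$model$traits[[trait]]
  ve <- if (is.null(tr$ve)) NA_real_ else tr$ve[env]
  if (!is.na(ve)) return(ve)
  h2 <- tr$h2[env]
  if (is.na(h2) || h2 <= 0)
    stop("trait ", trait, ": no error variance and no positive heritability")
  if (h2 == 1) return(0)
  G <- genotypic_values(pop_ref, trait, env)
  vg <- stats::var(G)
  vg * (1 - h2) / h2
}

#' Draw phenotypic values
#'
#' P = G + e with e ~ Normal(0, Ve) i.i.d. per individual. `Ve = 0` gives
#' P = G exactly.
#'
#' @param pop a `population`.
#' @param trait trait index.
#' @param env environment index.
#' @param ve error variance (nonnegative); typically from
#'   [calc_error_variance()] on the experiment's reference population.
#' @return the population with `values$P[[key]]` filled.
#' @export
calc_phenotypic_value <- function(pop, trait, env = 1L, ve) {
  if (ve < 0) stop("error variance must be nonnegative")
  pop <- calc_genotypic_value(pop, trait, env)
  key <- value_key(trait, env)
  G <- pop$values$G[[key]]
  e <- if (ve > 0) stats::rnorm(pop$size, 0, sqrt(ve)) else 0
  pop$values$P[[key]] <- G + e
  pop
}

#' Evaluate a composite trait
#'
#' Composite traits fold their expression left to right from the first
#' operand trait: ((T_first op1 T_1) op2 T_2) ... with operators + - * /.
#' Division by zero is flagged: affected individuals get `NaN`/`Inf` and a
#' warning names how many were affected.
#'
#' @param pop a `population` with the underlying genotypic values computed
#'   (computed on demand otherwise).
#' @param composite composite-trait index.
#' @param env environment index.
#' @param what `"G"` to fold genotypic values (default) or `"P"` for
#'   phenotypic values (which must have been computed).
#' @return numeric vector of composite values.
#' @export
calc_composite_trait <- function(pop, composite, env = 1L, what = c("G", "P")) {
  what <- match.arg(what)
  cp <- pop$model$composites[[composite]]
  if (is.null(cp)) stop("composite trait index out of range")
  get_vals <- function(trait) {
    if (what == "G") genotypic_values(pop, trait, env)
    else phenotypic_values(pop, trait, env)
  }
  acc <- get_vals(cp$first)
  for (i in seq_len(nrow(cp$ops))) {
    rhs <- get_vals(cp$ops$trait[i])
    op <- cp$ops$op[i]
    if (op == "/" && any(rhs == 0))
      warning("composite trait ", cp$name, ": division by zero for ",
              sum(rhs == 0), " individual(s)")
    acc <- switch(op,
                  "+" = acc + rhs,
                  "-" = acc - rhs,
                  "*" = acc * rhs,
                  "/" = acc / rhs)
  }
  acc
}

#' Rescale a value into \[0, 1\] by a trait range
#'
#' `(v - lowest) / (highest - lowest)`, clipped to \[0, 1\]. Used to put
#' population means of different genetic models on a common scale.
#'
#' @param v numeric vector.
#' @param lowest,highest range bounds (`lowest < highest`).
#' @return numeric vector in \[0, 1\].
#' @export
adjust_by_range <- function(v, lowest, highest) {
  if (highest <= lowest) stop("degenerate range: lowest >= highest")
  pmin(1, pmax(0, (v - lowest) / (highest - lowest)))
}
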