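---
title: "breedsim: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breedsim: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(breedsim)
```

breedsim is a forward-in-time simulator for population and quantitative
genetics and for breeding-program design. It separates three concerns: a
*genetic model* (what the genome and the genotype-to-phenotype map look
like), a *population* (who exists, with which phased genotypes), and
*operations* (crossing, mutation, evaluation, selection) that application
pipelines compose into experiments. This vignette explains the science
behind each part, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where more than one reasonable choice existed. It states no empirical
result that the package's tests do not themselves compute.

## The genetic model

A `genetic_model` holds environments (with occurrence frequencies in the
target population of environments), traits (per-environment broad-sense
heritability $H^2$ and/or error variance $V_e$), chromosomes, and ordered
loci. Each locus has a map position in centiMorgans, an allele count $k$, a
gene/marker flag, and optionally a $k \times (k-1)$ mutation-rate matrix
whose row $i$ lists the per-generation rates from allele $i$ to every other
allele in ascending allele order. Genotype-to-value maps attach to loci:

* **genes** give a value to each of the $k(k+1)/2$ unordered genotypes, per
  trait and environment;
* **epistasis networks** give a value to every genotype *combination* of two
  or more loci — contributions that cannot be decomposed into per-locus
  effects;
* **cytoplasm actions** attach trait effects to a maternally inherited
  cytoplasm type, alone (an independent effect) or interacting with nuclear
  loci;
* **fertility actions** give multiplicative female/male fertility factors
  (1 = normal, 0 = sterile) determined by cytoplasm and/or nuclear
  genotypes, assumed environment-independent.

All value arrays are flat vectors in one canonical order: unordered allele
pairs $(1,1), (1,2), \dots, (1,k), (2,2), \dots, (k,k)$ at a single locus
(`genotype_index()`), and the row-major product order with the *last listed
locus varying fastest* across loci (`combo_index()`). Fixing one canonical
order makes every published value array unambiguous; the enumeration is
asserted against brute-force oracles in the tests.

**Indexing.** Alleles, loci and genotype indices are 1-based both in files
and in memory. R is a 1-based language and the field's narration ("allele 1
mutates to allele 2 at rate …") is 1-based, so a 0-based internal convention
would only add translation errors at the boundary.

**Recombination fractions** between adjacent loci are derived from cM gaps
$d$ with Haldane's mapping function $r = \tfrac12(1 - e^{-2d/100})$ (no
crossover interference); an explicitly supplied $r$ overrides the
derivation, and the first locus of each chromosome gets $r = 0.5$ so a
single per-genome chain of switch events realizes both linkage and
independent assortment of chromosomes.

**Serialization** is JSON (via jsonlite), mirroring the model structure
key for key; `read_gmodel()` finalizes and validates, and
`write_gmodel()`/`read_gmodel()` round-trip exactly. YAML input was
considered and dropped: no YAML parser is available in the supported
dependency set, and JSON covers the need.

## Populations and the generation engine

A `population` stores phased diploid genotypes as two individuals-by-loci
integer matrices, plus cytoplasm indices and recorded parent ids. Founder
populations are created either from per-locus allele-frequency vectors —
each of the $2N$ allele copies drawn i.i.d., i.e. Hardy–Weinberg and linkage
equilibrium, the natural reading of "create a population from allele
frequencies" — or from explicit allele combinations with counts.

Gametes follow the Haldane model: per chromosome a fair coin picks the
starting haplotype and the active haplotype switches at each interval with
probability $r$. Random-union mating draws, for every progeny, a female and
a male gamete source independently and with replacement, each with
probability proportional to the individual's sex-specific fertility
(uniform when no fertility actions exist). Selfing is permitted. This is
exactly the idealized population of the inbreeding recursion
$F_t = 1-(1-\frac{1}{2N})^t$: two uniformly drawn gametes coincide in
origin-copy with probability $1/2N$. Progeny inherit the female parent's
cytoplasm. Doubled haploids double a single (already mutated) gamete, so DH
heterozygosity is exactly zero by construction.

**Mutation** applies once per generation to every newly formed population
(crossing operations call it automatically): each allele copy at each
mutating locus moves from allele $i$ to $j$ with probability $m_{ij}$, at
most one event per copy per generation — a documented approximation valid
for the small rates used throughout ($\le 0.02$). Cytoplasms mutate
analogously.

**Fertility semantics.** The platform defines fertility values but not how
they enter mating; multiplicative sex-specific individual weights on gamete
sources are the minimal consistent choice. Genotype-dependent *gametic*
(as opposed to parental) fertility would be a refinement, not attempted
here.

## Per-individual values

Genotypic value is the deterministic sum
$G = \sum_\text{genes} v + \sum_\text{networks} v + \sum_\text{cyt.\ actions} v$
over the components registered for the trait and environment (cytoplasm
actions contribute only to carriers). Phenotype is $P = G + e$,
$e \sim N(0, V_e)$. When a trait specifies $H^2$ instead of $V_e$, the
error variance is derived as $V_e = V_g (1 - H^2)/H^2$ from a reference
population's genotypic variance.

**Which reference population?** Two defensible policies exist and the
package implements both (`run_prs(ve_policy = )`):

* `"fixed"` derives $V_e$ once from the initial population and freezes it;
  selection then erodes realized heritability as variance is exhausted.
* `"per_cycle"` (default) re-derives $V_e$ from the current population each
  cycle, holding realized $H^2$ at its nominal value throughout.

The default was chosen because only the per-cycle policy reproduces
pure-line theory in the recurrent-selection case study: with a frozen
$V_e$, selection stalls before fixation (the acceptance tests measure a
plateau near 0.97 and a reverse-phase drift of ~0.06), whereas re-derivation
keeps selection effective as variance shrinks, populations fix completely
under a purely additive model, and downward selection without mutation has
no variation left to act on — the behavior the case study describes. This
matches how established breeding simulators treat input heritability as a
property of the evaluation system rather than of one historical population.

Composite traits fold left-to-right over underlying traits with
$+,-,\times,\div$; division by zero is flagged per individual rather than
silently propagated. Trait ranges rescale values to $[0,1]$ via
$(v - \min)/(\max - \min)$ for cross-model comparison.

## Population statistics and theory

`calc_pstatistics()` reports sample means and variances of $G$, allele and
cytoplasm frequencies (counted over $2N$ copies), per-locus gene diversity
$1-\sum_i p_i^2$, and an empirical additive/dominance decomposition:
breeding values are the fitted values of a joint least-squares regression
of $G$ on per-locus allele dosages ($V_A$ = their variance), and dominance
deviations are per-locus genotype-class means of the additive residual
($V_D$ = variance of their sum). Computing $V_A$/$V_D$ from the realized
population rather than from Hardy–Weinberg closed forms keeps them defined
after selection and under inbreeding; the textbook closed forms
($V_A = 2pq\alpha^2$ with $\alpha = a + d(q-p)$, $V_D = (2pqd)^2$) serve as
independent test oracles in exact-HWE populations.

The closed-form theory functions implement the standard results: the drift
recursion $F_t = 1-(1-\frac{1}{2N})^t(1-F_0)$; the one-step
mutation–drift recursion
$F_t = [\frac{1}{2N} + (1-\frac{1}{2N})F_{t-1}](1-u)^2$; its equilibrium
$\tilde F = 1/(1+4Nu)$ (via $1/(1-u)^2 \approx 1+2u$); and Ewens'
approximation for the expected number of distinct alleles,
$E(k) = \sum_{i=0}^{n-1} \theta/(\theta+i)$ with $\theta = 4Nu$. Two
conventions required a decision and are fixed here: the theoretical total
mutation rate of a $k$-allele locus with uniform pairwise rate $m$ is
$u = m(k-1)$, and the Ewens sample size is $n = 2N$ gene copies — the pair
of conventions that reproduces the published equilibrium table to its
printed precision (asserted for all 16 scenarios in the acceptance tests).

Two inbreeding estimators from subpopulation allele frequencies are
provided because they answer different questions: the heterozygosity
deficit $F = (H_{exp} - H_{obs})/H_{exp}$ measures divergence from a known
base population (used in the pure-drift study), while mean expected
homozygosity $F = \frac1m\sum_j\sum_i p_{ij}^2$ measures absolute identity
(used at mutation–drift equilibrium, where the base has been forgotten).
They are not identical in general and are asserted only where each is
appropriate. When $H_{exp} = 0$ the deficit estimator is undefined and
returns `NA`, never 0.

## Selection

`select_individuals()` implements truncation selection on any criterion:
`top`, `bottom`, a `middle` mode (a contiguous rank window centered on the
median rank $\lceil (n+1)/2 \rceil$ — "individuals with medium trait
values" admits more than one reading; the rank-window rule is documented
and deterministic), and `random`. Ties break by original index, so runs are
seed-reproducible. `select_among_families()` ranks families by their mean
criterion value.

## Application pipelines

**Drift (`run_drift`)** creates a base population with $k$ equally frequent
alleles at one locus and advances $T$ generations of random-union mating
for $R$ replicate runs, recording allele frequencies each generation; the
summary overlays both inbreeding estimators, retained-allele counts and the
drift theory trajectory.

**Recurrent selection (`run_prs`)** evaluates 100 candidates per cycle by
mass selection (PS) or by family means (S1 selfed families; S2 families
selfed for two generations through one random S1 member; HS half-sib
families from random distinct mates), selects the best 20 units (worst,
in the reverse phase) and random-mates to the next cycle. The published
study leaves the selection intensity and family size open; 20/100 selected
and 10 members per family are desk-scale defaults that keep the method
contrasts visible, and are configurable. For the family methods the
*members of the selected families* are pooled and inter-mated. The
alternative — re-using the family parents — was implemented first and
rejected: measured head-to-head, a half-sib family mean of 10 replicates
predicts its parent's breeding value with covariance $V_A/2$ and strongly
reduced noise, making HS *faster* than PS, the opposite of half-sib
theory's $V_A/4$ and of the case study's ordering. Recombining family
members transmits exactly the member–family-mean covariance $V_A/4$ and
restores the expected ordering, which the acceptance tests verify
cycle-by-cycle.

**Hybrid breeding (`run_hybrid`)** maintains two heterotic groups of 50
inbred lines, makes 100 biparental crosses in the improved group, derives
100 DHs per cross, and selects 5% then 10% of the 10,000 DH lines on
testcross performance with a fixed tester from the opposite group. Because
DH lines and testers are fully homozygous and the hybrid model is
mutation-free, every testcross progeny is the identical F1, so the
criterion is computed as the F1's genotypic value directly — the mean of
any number of simulated testcross progeny equals it exactly. Retained
lines are evaluated three ways: testcrosses, all single crosses with the
opposite group, and per se.

## Synthetic data: what the generators emulate

* `drift_model(k, m)`: one neutral multi-allelic locus, uniform pairwise
  mutation — the infinite-alleles idealization truncated to $k$ alleles.
* `ad_model(kind)`: ten unlinked biallelic genes with genotype values drawn
  Uniform(0,1) — `AD0` forces the heterozygote to midparent (pure
  additivity), `AD1` draws it freely (dominance, possibly overdominance),
  `ADE` adds five two-locus epistasis networks over disjoint pairs of the
  gene loci. Broad-sense $H^2 = 0.2$; optional mutation at 0.02 forward /
  0.01 reverse. Trait ranges use per-component extremes, so epistatic
  models need not attain their range endpoints jointly — which is why
  selected populations under `ADE` plateau below 1 on the adjusted scale.
* `hybrid_model()`: 100 biallelic gene loci, 10 per chromosome at 10 cM
  spacing. Homozygote values are Uniform(0,1); the heterozygote is
  midparent plus a dominance deviation with degree $\delta \sim U(-1,1)$
  (no overdominance). Dominance is essential here: under pure additivity
  every tester ranks candidate lines identically and tester choice could
  not matter, contradicting the phenomenon under study. $\delta$'s range is
  the maximal no-overdominance choice and is fixed once.

What a green test does *not* establish: the generators draw architectures
far simpler than real crops — no genotype-by-environment interaction in the
fixtures, no linkage disequilibrium in founders, no minor-allele frequency
spectrum, equal-effect-scale loci, and neutral markers only. Conclusions
transfer to the mechanisms simulated, not to any particular germplasm.

## Numerical choices and degenerate inputs

Environment frequencies must sum to 1 within $10^{-9}$, as must
allele-frequency vectors. Mutation rows must sum below 1. Haldane
conversion is validated by its closed inverse $d = -50\ln(1-2r)$ to
$10^{-9}$. Selection with missing criterion values is an error, not a
silent drop. An empty population cannot be crossed or summarized. The
one-mutation-per-copy approximation and the $N - 1$ sample-variance
convention in $V_g$ are the only deliberate numerical approximations.
Monte-Carlo tests use 3–4 standard-error windows; the phenotype
Kolmogorov–Smirnov check at $\alpha = 0.01$ has a corresponding design
flake rate under reseeding (the suite's seeds are fixed).

## Known limitations

Non-overlapping generations only; no sex chromosomes; no interference
mapping functions other than Haldane; fertility is parental, not gametic;
no migration or admixture operators; the hybrid pipeline improves one
heterotic group against a static partner. These boundaries mirror the
scope of the case studies the package reproduces.
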