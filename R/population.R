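## Core data model: mutation registry, haplotypes, populations.
##
## A haplotype is an integer vector of mutation ids, kept sorted by
## (position, id).  Mutation identity -- not position -- defines
## homozygosity: two independent mutation events at the same site are
## distinct alleles.  The registry maps ids to positions, selection
## coefficients and origin generations; ids are consecutive from 1 and
## never reused within a run.

#' Create an empty mutation registry
#'
#' The registry records, for every mutation id ever created in a run, its
#' 0-based base-pair position, selection coefficient and origin generation.
#' Ids are consecutive integers starting at 1 and are never reused, so a
#' registry only grows; mutations lost or fixed keep their entry.
#'
#' @return An environment of class `pod_registry` with numeric vectors
#'   `pos` and `s` and integer vector `origin`, indexed by mutation id.
#' @seealso [register_mutations()], [mutation_records()]
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$pos <- numeric(0)
  reg$s <- numeric(0)
  reg$origin <- integer(0)
  class(reg) <- "pod_registry"
  reg
}

#' Register new mutations and obtain fresh ids
#'
#' @param registry A [new_registry()] environment.
#' @param pos Numeric vector of 0-based positions in `[0, L)`.
#' @param s Selection coefficients in `(-1, 0]` (recycled).
#' @param origin Origin generation(s), integer >= 0 (recycled).
#' @return Integer vector of newly assigned mutation ids.
#' @export
register_mutations <- function(registry, pos, s, origin = 0L) {
  stopifnot(inherits(registry, "pod_registry"))
  k <- length(pos)
  if (k == 0L) return(integer(0))
  if (any(!is.finite(pos)) || any(pos < 0))
    stop("mutation positions must be finite and >= 0", call. = FALSE)
  s <- rep_len(as.numeric(s), k)
  if (any(s > 0 | s <= -1))
    stop("selection coefficients must lie in (-1, 0]", call. = FALSE)
  ids <- length(registry$pos) + seq_len(k)
  registry$pos <- c(registry$pos, as.numeric(pos))
  registry$s <- c(registry$s, s)
  registry$origin <- c(registry$origin, rep_len(as.integer(origin), k))
  as.integer(ids)
}

#' Look up mutation records by id
#'
#' @param registry A [new_registry()] environment.
#' @param ids Integer mutation ids; default all registered mutations.
#' @return A data frame with columns `id`, `pos`, `s`, `origin`.
#' @export
mutation_records <- function(registry, ids = NULL) {
  stopifnot(inherits(registry, "pod_registry"))
  if (is.null(ids)) ids <- seq_along(registry$pos)
  check_ids(registry, ids)
  data.frame(id = as.integer(ids), pos = registry$pos[ids],
             s = registry$s[ids], origin = registry$origin[ids])
}

check_ids <- function(registry, ids) {
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || any(ids < 1L) ||
                      any(ids > length(registry$pos))))
    stop("unknown mutation id", call. = FALSE)
  ids
}

## order a haplotype id vector by (position, id)
sort_haplotype <- function(ids, registry) {
  ids <- as.integer(ids)
  if (length(ids) < 2L) return(ids)
  ids[order(registry$pos[ids], ids)]
}

#' Multiplicative fitness under full recessivity
#'
#' An individual's fitness is the product of `(1 + s_i)` over the set `H`
#' of mutations present on *all* of its chromosome copies (for tetraploids,
#' all four).  Mutations absent from any copy are completely masked and
#' contribute nothing, so fitness lies in `(0, 1]` for `s` in `(-1, 0]`,
#' and equals 1 exactly when no mutation is homozygous.
#'
#' @param copies A non-empty list of haplotypes (integer vectors of
#'   mutation ids), one per chromosome copy.
#' @param registry The mutation registry mapping ids to coefficients.
#' @return A single fitness value in `(0, 1]`.
#' @examples
#' reg <- new_registry()
#' m <- register_mutations(reg, pos = 1000, s = -0.005)
#' compute_fitness(list(m, m), reg)            # homozygous: 0.995
#' compute_fitness(list(m, integer(0)), reg)   # masked: 1
#' @export
compute_fitness <- function(copies, registry) {
  if (!is.list(copies) || length(copies) == 0L)
    stop("'copies' must be a non-empty list of haplotypes", call. = FALSE)
  homozygous <- Reduce(intersect, lapply(copies, check_ids,
                                         registry = registry))
  prod(1 + registry$s[homozygous])
}

#' Construct a mutation-free founder population
#'
#' Populations start without any mutations (no burn-in), matching a study
#' design that follows the approach to equilibrium from the moment of
#' population formation.
#'
#' @param N Number of individuals.
#' @param ploidy 2 or 4.
#' @param L Chromosome length in bp.
#' @return An object of class `pod_population`: a list with elements
#'   `N`, `ploidy`, `L`, `generation`, `substitutions`, `haplotypes`
#'   (a list of `ploidy * N` id vectors; copies of individual `i` occupy
#'   slots `(i-1)*ploidy + 1:ploidy`) and `registry`.
#' @export
new_population <- function(N, ploidy, L = 1e6) {
  N <- as.integer(N)
  stopifnot(N >= 1, ploidy %in% c(2, 4), L >= 1)
  structure(
    list(N = N, ploidy = as.integer(ploidy), L = as.numeric(L),
         generation = 0L, substitutions = 0L,
         haplotypes = rep(list(integer(0)), N * ploidy),
         registry = new_registry()),
    class = "pod_population")
}

#' Build a deterministic population from explicit haplotype contents
#'
#' Test-fixture constructor: the caller supplies the mutation table and,
#' for every chromosome copy, the rows of that table it carries.  Used by
#' the gamete-law enumeration checks and fitness tests, and exported for
#' constructing arbitrary starting states.
#'
#' @param copies A list of integer vectors, one per chromosome copy (so its
#'   length must be a multiple of `ploidy`); each vector indexes rows of
#'   `mutations`.  Duplicated indices within one copy are rejected.
#' @param mutations A data frame with columns `pos` (0-based, in `[0, L)`)
#'   and `s` (in `(-1, 0]`); row `i` becomes mutation id `i`.
#' @param ploidy 2 or 4.
#' @param L Chromosome length in bp.
#' @return A `pod_population` whose copy `k` carries exactly
#'   `mutations[copies[[k]], ]`.
#' @examples
#' # two complementary single-mutation haplotypes, one AAaa tetraploid
#' muts <- data.frame(pos = c(100, 900), s = -0.005)
#' pop <- fixture_population(list(1L, 1L, 2L, 2L), muts, ploidy = 4)
#' @export
fixture_population <- function(copies, mutations, ploidy, L = 1e6) {
  stopifnot(is.list(copies), ploidy %in% c(2, 4))
  if (length(copies) %% ploidy != 0L || length(copies) == 0L)
    stop("length(copies) must be a positive multiple of 'ploidy'",
         call. = FALSE)
  if (!is.data.frame(mutations) || !all(c("pos", "s") %in% names(mutations)))
    stop("'mutations' must be a data frame with columns 'pos' and 's'",
         call. = FALSE)
  if (any(mutations$pos < 0 | mutations$pos >= L))
    stop("mutation positions must lie in [0, L)", call. = FALSE)
  N <- length(copies) %/% ploidy
  pop <- new_population(N, ploidy, L)
  ids <- register_mutations(pop$registry, mutations$pos, mutations$s,
                            origin = 0L)
  pop$haplotypes <- lapply(copies, function(ix) {
    ix <- as.integer(ix)
    if (anyNA(ix) || any(ix < 1L | ix > nrow(mutations)))
      stop("copy refers to a mutation row that does not exist",
           call. = FALSE)
    if (anyDuplicated(ix))
      stop("duplicate mutation on one chromosome copy", call. = FALSE)
    sort_haplotype(ids[ix], pop$registry)
  })
  pop
}

#' Extract the chromosome copies of one individual
#'
#' @param population A `pod_population`.
#' @param i Individual index in `1:N`.
#' @return A list of `ploidy` haplotype id vectors.
#' @export
individual_copies <- function(population, i) {
  stopifnot(inherits(population, "pod_population"),
            i >= 1, i <= population$N)
  p <- population$ploidy
  population$haplotypes[(i - 1L) * p + seq_len(p)]
}

#' Fitness of every individual in a population
#'
#' Pure-R evaluation of the multiplicative recessive fitness model for each
#' individual; the simulation engine computes the same quantity internally,
#' and the two routes are cross-checked in the test suite.
#'
#' @param population A `pod_population`.
#' @return Numeric vector of length `N`.
#' @export
population_fitness <- function(population) {
  stopifnot(inherits(population, "pod_population"))
  vapply(seq_len(population$N), function(i)
    compute_fitness(individual_copies(population, i), population$registry),
    numeric(1))
}

## per-id carrier counts over the whole population (named by id, only ids
## present on >= 1 copy)
carrier_counts <- function(population) {
  all_ids <- unlist(population$haplotypes, use.names = FALSE)
  if (length(all_ids) == 0L)
    return(integer(0))
  counts <- tabulate(all_ids, nbins = length(population$registry$pos))
  present <- which(counts > 0L)
  setNames(counts[present], present)
}

#' Population frequency of one mutation
#'
#' @param population A `pod_population`.
#' @param mutation_id A single registered mutation id.
#' @return Carrier haplotypes divided by `ploidy * N`, in `[0, 1]`.
#' @export
allele_frequency <- function(population, mutation_id) {
  stopifnot(inherits(population, "pod_population"), length(mutation_id) == 1)
  mutation_id <- check_ids(population$registry, mutation_id)
  carriers <- sum(vapply(population$haplotypes,
                         function(h) mutation_id %in% h, logical(1)))
  carriers / (population$ploidy * population$N)
}

#' Remove fixed mutations from the segregating pool
#'
#' A mutation present on all `ploidy * N` haplotypes is fixed: it no longer
#' responds to selection (every genotype is homozygous for it) and is
#' removed from every haplotype, with the substitution counter incremented.
#' Fitness thereafter reflects segregating load only.
#'
#' @param population A `pod_population`.
#' @return A list with elements `population` (fixed mutations removed,
#'   substitution count updated) and `removed` (number of substitutions
#'   made by this call).
#' @export
remove_fixed <- function(population) {
  stopifnot(inherits(population, "pod_population"))
  counts <- carrier_counts(population)
  total <- population$ploidy * population$N
  fixed <- as.integer(names(counts)[counts == total])
  if (length(fixed)) {
    population$haplotypes <- lapply(population$haplotypes,
                                    function(h) h[!(h %in% fixed)])
    population$substitutions <- population$substitutions + length(fixed)
  }
  list(population = population, removed = length(fixed))
}

#' @export
print.pod_population <- function(x, ...) {
  counts <- carrier_counts(x)
  total <- x$ploidy * x$N
  seg <- sum(counts > 0L & counts < total)
  cat(sprintf("pod_population: N = %d, ploidy = %d, L = %g bp\n",
              x$N, x$ploidy, x$L))
  cat(sprintf("  generation %d; %d segregating mutations; %d substitutions\n",
              x$generation, seg, x$substitutions))
  w <- population_fitness(x)
  cat(sprintf("  mean fitness %.6g (range %.6g-%.6g)\n",
              mean(w), min(w), max(w)))
  invisible(x)
}
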