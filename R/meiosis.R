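## Gamete formation: crossover placement, recombination, bivalent pairing,
## and mutation.  These are the reference (pure-R) implementations of the
## meiosis model; the compiled engine used by wf_run() implements the same
## semantics and is cross-checked against these in the tests.

#' Draw a crossover plan for one bivalent
#'
#' The number of crossovers between a pair of chromosomes is
#' Poisson(`rho * L`) and each falls uniformly on one of the `L - 1`
#' inter-base boundaries; there is no crossover interference.  A boundary
#' hit an even number of times produces no net exchange, so the returned
#' breakpoints are the strictly increasing boundaries hit an odd number of
#' times.  `start_copy` is the chromatid (1 or 2) the gamete chromosome
#' begins copying from, chosen by a fair coin.
#'
#' @param rho Per-bp recombination rate (>= 0).
#' @param L Chromosome length in bp (>= 1).
#' @return An object of class `crossover_plan`: list with integer
#'   `breakpoints` (strictly increasing, in `1:(L-1)`) and `start_copy`.
#' @examples
#' set.seed(1)
#' draw_crossovers(1e-7, 1e6)  # mean 0.1 crossovers
#' @export
draw_crossovers <- function(rho, L) {
  if (!is.finite(rho) || rho < 0)
    stop("'rho' must be a non-negative per-bp rate", call. = FALSE)
  if (!is.finite(L) || L < 1)
    stop("'L' must be >= 1", call. = FALSE)
  n <- rpois(1L, rho * L)
  bp <- integer(0)
  if (n > 0L && L > 1) {
    hits <- 1L + as.integer(floor(runif(n) * (L - 1)))
    multiplicity <- table(hits)
    bp <- sort(as.integer(names(multiplicity)[multiplicity %% 2L == 1L]))
  }
  structure(list(breakpoints = bp,
                 start_copy = if (runif(1) < 0.5) 1L else 2L),
            class = "crossover_plan")
}

#' Recombine two haplotypes according to a crossover plan
#'
#' Walks the chromosome left to right, copying mutations from the current
#' template and switching templates at each breakpoint.  A mutation at
#' position `p` belongs to the segment left of breakpoint `b` iff `p < b`
#' (breakpoints sit on inter-base boundaries).  No mutations are invented
#' or lost relative to the templates' interval contents.
#'
#' @param hapA,hapB Haplotypes (integer id vectors) to recombine.
#' @param plan A [draw_crossovers()] plan; `start_copy = 1` starts on
#'   `hapA`.
#' @param registry Registry supplying mutation positions.
#' @return The recombinant haplotype, sorted by (position, id).
#' @export
recombine <- function(hapA, hapB, plan, registry) {
  stopifnot(inherits(plan, "crossover_plan"))
  hapA <- check_ids(registry, hapA)
  hapB <- check_ids(registry, hapB)
  bp <- plan$breakpoints
  if (length(bp) == 0L)
    return(if (plan$start_copy == 1L) hapA else hapB)
  # segment index of a position = number of breakpoints <= position;
  # templates alternate across segments starting from start_copy
  segA <- findInterval(registry$pos[hapA], bp)
  segB <- findInterval(registry$pos[hapB], bp)
  fromA <- (segA %% 2L == 0L) == (plan$start_copy == 1L)
  fromB <- (segB %% 2L == 0L) != (plan$start_copy == 1L)
  sort_haplotype(c(hapA[fromA], hapB[fromB]), registry)
}

## the three perfect matchings of copies {1,2,3,4} into two bivalents
bivalent_matchings <- list(
  list(c(1L, 2L), c(3L, 4L)),
  list(c(1L, 3L), c(2L, 4L)),
  list(c(1L, 4L), c(2L, 3L)))

#' Draw a random bivalent pairing of four homologs
#'
#' Under strictly bivalent tetrasomic meiosis the four chromosome copies
#' are partitioned into two pairs; all three perfect matchings are equally
#' likely.  Pairing is by copy index, never by content.
#'
#' @return One of the three matchings: a list of two integer pairs
#'   partitioning `1:4`.
#' @examples
#' set.seed(1)
#' pair_bivalents()
#' @export
pair_bivalents <- function() {
  bivalent_matchings[[sample.int(3L, 1L)]]
}

#' Add new mutations to a haplotype
#'
#' Draws a Poisson(`mu * L`) number of new mutation events at uniform
#' positions in `[0, L)`, each receiving a fresh id from the registry with
#' coefficient `s` and the given origin generation.  Independent events at
#' an already-mutated site are stacked as distinct alleles.
#'
#' @param hap Haplotype to mutate (integer id vector).
#' @param mu Per-bp mutation rate (>= 0).
#' @param L Chromosome length in bp.
#' @param registry Registry to be extended (modified in place).
#' @param s Selection coefficient for the new mutations.
#' @param generation Origin generation recorded for the new mutations.
#' @return The haplotype with new mutations inserted, sorted by
#'   (position, id).
#' @export
mutate_haplotype <- function(hap, mu, L, registry, s, generation = 0L) {
  if (!is.finite(mu) || mu < 0)
    stop("'mu' must be a non-negative per-bp rate", call. = FALSE)
  k <- rpois(1L, mu * L)
  if (k == 0L) return(hap)
  pos <- floor(runif(k) * L)
  ids <- register_mutations(registry, pos, s, generation)
  sort_haplotype(c(hap, ids), registry)
}

#' Form one gamete from a parent
#'
#' Diploid parents produce a one-chromosome gamete: a recombinant of their
#' two copies under a fresh [draw_crossovers()] plan.  Tetraploid parents
#' produce a two-chromosome gamete: the four copies are paired into two
#' bivalents uniformly at random ([pair_bivalents()]) and each bivalent
#' independently contributes one recombinant chromosome (its own crossover
#' plan and chromatid coin).  New mutations are then added to every gamete
#' chromosome.  Each call draws a fresh pairing and fresh plans, matching
#' per-offspring gamete sampling in Wright-Fisher engines.
#'
#' @param parent_copies List of `ploidy` haplotypes (the parent's copies).
#' @param params A [sim_params()] object (uses `mu`, `rho`, `L`, `s`).
#' @param registry Mutation registry (extended in place by new mutations).
#' @param generation Origin generation for new mutations.
#' @return A list of 1 (diploid) or 2 (tetraploid) haplotypes.
#' @export
make_gamete <- function(parent_copies, params, registry, generation = 0L) {
  stopifnot(is.list(parent_copies))
  if (length(parent_copies) != params$ploidy)
    stop("parent has ", length(parent_copies),
         " copies but params$ploidy = ", params$ploidy, call. = FALSE)
  one_chromosome <- function(hapA, hapB) {
    plan <- draw_crossovers(params$rho, params$L)
    mutate_haplotype(recombine(hapA, hapB, plan, registry),
                     params$mu, params$L, registry, params$s, generation)
  }
  if (params$ploidy == 2L) {
    list(one_chromosome(parent_copies[[1L]], parent_copies[[2L]]))
  } else {
    pairing <- pair_bivalents()
    lapply(pairing, function(pair)
      one_chromosome(parent_copies[[pair[1L]]], parent_copies[[pair[2L]]]))
  }
}
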