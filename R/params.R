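#' Simulation parameters for a single Wright-Fisher replicate
#'
#' Bundles and validates the full parameterization of one forward-simulation
#' replicate.  All rates are per base pair per generation; the chromosome is
#' a single linear sequence of `L` base pairs with 0-based positions in
#' `[0, L)`.
#'
#' @param N Population size (number of individuals), constant over the run.
#'   Must be at least 2.
#' @param ploidy Number of chromosome copies per individual: 2 (diploid) or
#'   4 (autotetraploid with strictly bivalent, tetrasomic meiosis).
#' @param mu Per-base-pair mutation rate. New mutations arise on each gamete
#'   chromosome as a Poisson(`mu * L`) number of events at uniform positions.
#' @param rho Per-base-pair recombination rate. Crossovers within each
#'   bivalent (or diploid homolog pair) are Poisson(`rho * L`).
#' @param s Selection coefficient shared by every mutation in the run;
#'   must lie in `(-1, 0]`.  Mutations are fully recessive: `s` is expressed
#'   only when a mutation is present on all `ploidy` copies.
#' @param generations Number of non-overlapping generations to simulate.
#' @param L Chromosome length in base pairs (default 1 Mb).
#' @param seed Optional integer RNG seed; when supplied the run is exactly
#'   reproducible.  `NULL` uses (and advances) the session RNG.
#' @param selfing_allowed If `TRUE` (default) the two parents of an offspring
#'   are drawn independently, so incidental selfing can occur; if `FALSE`
#'   the second parent is redrawn until distinct.
#' @param snapshot_generations Integer vector of generations (in
#'   `1:generations`) at which the fitness values of the realized offspring
#'   cohort are recorded, e.g. for offspring-fitness density plots.
#'
#' @return An object of class `pod_params` (a validated named list).
#' @examples
#' p <- sim_params(N = 100, ploidy = 4, mu = 1e-7, rho = 1e-10,
#'                 s = -0.005, generations = 100, seed = 1)
#' p
#' @export
sim_params <- function(N, ploidy, mu, rho, s, generations, L = 1e6,
                       seed = NULL, selfing_allowed = TRUE,
                       snapshot_generations = integer(0)) {
  stopifnot(length(N) == 1, length(ploidy) == 1, length(mu) == 1,
            length(rho) == 1, length(s) == 1, length(generations) == 1,
            length(L) == 1)
  N <- as.integer(N)
  generations <- as.integer(generations)
  if (is.na(N) || N < 2L)
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (!ploidy %in% c(2, 4))
    stop("'ploidy' must be 2 or 4", call. = FALSE)
  if (!is.finite(L) || L < 1)
    stop("'L' must be a positive chromosome length in bp", call. = FALSE)
  if (!is.finite(mu) || mu < 0)
    stop("'mu' must be a non-negative per-bp mutation rate", call. = FALSE)
  if (!is.finite(rho) || rho < 0)
    stop("'rho' must be a non-negative per-bp recombination rate",
         call. = FALSE)
  if (!is.finite(s) || s > 0 || s <= -1)
    stop("'s' must lie in (-1, 0]: the model is deleterious-only and ",
         "fitness must stay positive", call. = FALSE)
  if (is.na(generations) || generations < 1L)
    stop("'generations' must be an integer >= 1", call. = FALSE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be a single integer", call. = FALSE)
  }
  snapshot_generations <- as.integer(snapshot_generations)
  if (any(is.na(snapshot_generations)) ||
      any(snapshot_generations < 1L | snapshot_generations > generations))
    stop("'snapshot_generations' must lie in 1:generations", call. = FALSE)
  structure(
    list(N = N, ploidy = as.integer(ploidy), L = as.numeric(L),
         mu = as.numeric(mu), rho = as.numeric(rho), s = as.numeric(s),
         generations = generations, seed = seed,
         selfing_allowed = isTRUE(selfing_allowed),
         snapshot_generations = snapshot_generations),
    class = "pod_params")
}

#' @export
print.pod_params <- function(x, ...) {
  cat("Wright-Fisher simulation parameters (pod_params)\n")
  cat(sprintf("  N = %d, ploidy = %d, L = %g bp\n", x$N, x$ploidy, x$L))
  cat(sprintf("  mu = %g /bp (genome-wide %.4g), rho = %g /bp (map length %.4g)\n",
              x$mu, x$mu * x$L, x$rho, x$rho * x$L))
  cat(sprintf("  s = %g (fully recessive), generations = %d\n",
              x$s, x$generations))
  cat(sprintf("  seed = %s, selfing %s\n",
              if (is.null(x$seed)) "<session RNG>" else x$seed,
              if (x$selfing_allowed) "allowed" else "excluded"))
  if (length(x$snapshot_generations))
    cat("  snapshots at generations:",
        paste(x$snapshot_generations, collapse = ", "), "\n")
  invisible(x)
}
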