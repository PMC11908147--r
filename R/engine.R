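## R surface of the compiled Wright-Fisher engine.

traj_colnames <- c("generation", "mean_pop_fitness", "sd_pop_fitness",
                   "mean_parent_fitness", "median_allele_freq",
                   "n_segregating", "n_substitutions")

## run set.seed(seed) for the duration of `expr`, restoring the session
## RNG state afterwards; seed = NULL leaves the session RNG in charge
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

as_traj_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- traj_colnames
  df$generation <- as.integer(df$generation)
  df$n_segregating <- as.integer(df$n_segregating)
  df$n_substitutions <- as.integer(df$n_substitutions)
  df
}

engine_call <- function(population, params, generations, snapshot_abs) {
  reg <- population$registry
  engine_run(population$haplotypes, reg$pos, reg$s, reg$origin,
             population$N, population$ploidy, population$L,
             params$mu, params$rho, params$s, generations,
             params$selfing_allowed, as.integer(snapshot_abs),
             population$generation, population$substitutions)
}

engine_unpack <- function(population, res, generations) {
  reg <- population$registry
  reg$pos <- res$pos
  reg$s <- res$s
  reg$origin <- res$origin
  population$haplotypes <- res$haplotypes
  population$substitutions <- res$substitutions
  population$generation <- population$generation + generations
  list(population = population, trajectory = as_traj_df(res$trajectory),
       snapshots = res$snapshots)
}

#' Advance a population by one Wright-Fisher generation
#'
#' Produces exactly `N` offspring.  Each offspring's two parents are drawn
#' independently with probability proportional to fitness (the same
#' individual can be drawn twice when `selfing_allowed`); each parent
#' contributes one gamete ([make_gamete()] semantics), fixed mutations are
#' then removed, and a row of per-generation statistics is recorded.
#'
#' @param population A `pod_population` consistent with `params`.
#' @param params A [sim_params()] object.  `params$seed` is ignored here;
#'   the call uses (and advances) the session RNG so that repeated steps
#'   continue one stream.
#' @return A list with the new `population` and `stats`, a one-row data
#'   frame with columns `generation`, `mean_pop_fitness`,
#'   `sd_pop_fitness`, `mean_parent_fitness`, `median_allele_freq`,
#'   `n_segregating` and `n_substitutions`.  `mean_parent_fitness`
#'   averages over the `2N` parent draws with multiplicity; population
#'   fitness summaries describe the offspring cohort after fixed-mutation
#'   removal.
#' @export
wf_step <- function(population, params) {
  stopifnot(inherits(population, "pod_population"),
            inherits(params, "pod_params"))
  if (population$N != params$N || population$ploidy != params$ploidy)
    stop("population and params disagree on N or ploidy", call. = FALSE)
  res <- engine_call(population, params, 1L, integer(0))
  out <- engine_unpack(population, res, 1L)
  list(population = out$population, stats = out$trajectory)
}

#' Run a full forward simulation replicate
#'
#' Initializes `N` mutation-free individuals (no burn-in: the run follows
#' the approach to equilibrium from population formation) and iterates
#' [wf_step()] dynamics for `params$generations` generations, recording one
#' statistics row per generation and, at each requested snapshot
#' generation, the fitness values of the realized offspring cohort before
#' any further selection.  With a non-`NULL` seed the trajectory is exactly
#' reproducible and the session RNG state is left untouched.
#'
#' @param params A [sim_params()] object.
#' @param population Optional starting `pod_population` (default: a fresh
#'   mutation-free founder population).  Must match `N` and `ploidy`.
#' @return An object of class `pod_sim`: a list with `params`,
#'   `trajectory` (data frame, one row per generation), `population`
#'   (final state), and `snapshots` (named list of fitness vectors).
#' @examples
#' sim <- wf_run(sim_params(N = 50, ploidy = 2, mu = 1e-7, rho = 1e-8,
#'                          s = -0.005, generations = 200, seed = 42))
#' summary(sim)
#' @export
wf_run <- function(params, population = NULL) {
  stopifnot(inherits(params, "pod_params"))
  if (is.null(population)) {
    population <- new_population(params$N, params$ploidy, params$L)
  } else {
    stopifnot(inherits(population, "pod_population"))
    if (population$N != params$N || population$ploidy != params$ploidy)
      stop("population and params disagree on N or ploidy", call. = FALSE)
  }
  snapshot_abs <- population$generation + params$snapshot_generations
  res <- with_seed(params$seed,
                   engine_call(population, params, params$generations,
                               snapshot_abs))
  out <- engine_unpack(population, res, params$generations)
  structure(list(params = params, trajectory = out$trajectory,
                 population = out$population, snapshots = out$snapshots),
            class = "pod_sim")
}

#' Fitness-proportional parent sampling
#'
#' Reference implementation of the engine's parent-selection rule: index
#' `i` is returned with probability `w_i / sum(w)`.
#'
#' @param population A `pod_population`.
#' @param n Number of independent draws.
#' @return Integer vector of `n` individual indices in `1:N`.
#' @export
select_parent <- function(population, n = 1L) {
  w <- population_fitness(population)
  if (all(w <= 0))
    stop("degenerate population: total fitness is zero", call. = FALSE)
  sample.int(population$N, n, replace = TRUE, prob = w)
}

#' @export
print.pod_sim <- function(x, ...) {
  cat(sprintf("pod_sim: %d generations, N = %d, ploidy = %d\n",
              nrow(x$trajectory), x$params$N, x$params$ploidy))
  cat(sprintf("  mu = %g, rho = %g, s = %g, seed = %s\n",
              x$params$mu, x$params$rho, x$params$s,
              if (is.null(x$params$seed)) "<session>" else x$params$seed))
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("  final: mean fitness %.4f, median allele freq %.3f, %d segregating, %d substitutions\n",
              last$mean_pop_fitness, last$median_allele_freq,
              last$n_segregating, last$n_substitutions))
  invisible(x)
}

#' @export
summary.pod_sim <- function(object, window = min(1000L, nrow(object$trajectory)), ...) {
  tr <- object$trajectory
  win <- tail(tr, window)
  out <- list(
    params = object$params,
    generations = nrow(tr),
    window = range(win$generation),
    window_mean_fitness = mean(win$mean_pop_fitness),
    window_mean_parent_fitness = mean(win$mean_parent_fitness),
    window_median_freq_mean = mean(win$median_allele_freq),
    window_median_freq_sd = sd(win$median_allele_freq),
    final_segregating = tr$n_segregating[nrow(tr)],
    substitutions = tr$n_substitutions[nrow(tr)])
  class(out) <- "summary.pod_sim"
  out
}

#' @export
print.summary.pod_sim <- function(x, ...) {
  cat(sprintf("Wright-Fisher run: %d generations (N = %d, ploidy = %d)\n",
              x$generations, x$params$N, x$params$ploidy))
  cat(sprintf("Assessment window: generations %d-%d\n",
              x$window[1], x$window[2]))
  cat(sprintf("  mean population fitness  %.4f\n", x$window_mean_fitness))
  cat(sprintf("  mean parent fitness      %.4f\n",
              x$window_mean_parent_fitness))
  cat(sprintf("  median allele frequency  %.3f (sd %.3f)\n",
              x$window_median_freq_mean, x$window_median_freq_sd))
  cat(sprintf("  segregating mutations    %d; substitutions %d\n",
              x$final_segregating, x$substitutions))
  invisible(x)
}

#' Plot a simulation trajectory
#'
#' Two-panel base-graphics display: mean population and mean parent
#' fitness per generation, and the median segregating allele frequency.
#'
#' @param x A `pod_sim` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.pod_sim <- function(x, ...) {
  tr <- x$trajectory
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(oldpar))
  graphics::matplot(tr$generation,
                    cbind(tr$mean_pop_fitness, tr$mean_parent_fitness),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "generation", ylab = "mean fitness", ...)
  graphics::legend("bottomleft", c("population", "parents"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  graphics::plot(tr$generation, tr$median_allele_freq, type = "l",
                 xlab = "generation", ylab = "median allele frequency",
                 ylim = c(0, max(0.5, tr$median_allele_freq)))
  invisible(x)
}
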