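## Parameter-grid experiments: grid expansion, replicate seeding, sweep
## execution with incremental results, and per-combination aggregation.

#' Configure a parameter sweep
#'
#' Defines a full-factorial grid over population size, ploidy, mutation
#' rate, recombination rate and selection coefficient, with a fixed number
#' of replicates per combination.  Defaults mirror the grid values used in
#' the study this simulator reproduces (they make 720 combinations x 10
#' replicates at 10,000 generations -- scale down for interactive use).
#'
#' @param N,ploidy,mu,rho,s Non-empty vectors of parameter values (same
#'   constraints as in [sim_params()]).
#' @param replicates Replicates per combination (>= 1; default 10).
#' @param generations Generations per run (default 10,000).
#' @param L Chromosome length in bp.
#' @param base_seed Integer from which each run's seed is derived
#'   reproducibly (distinct per combination x replicate).
#' @param aggregation_generation Generation whose statistics feed the
#'   per-run result row (default: the final generation).
#' @param selfing_allowed Passed to [sim_params()].
#' @param pod_window,pod_freq_threshold,pod_stability_threshold
#'   [classify_pod()] settings applied to every run; the effective window
#'   is capped at the trajectory length.
#' @return An object of class `pod_sweep_config`.
#' @export
sweep_config <- function(N = c(100L, 500L),
                         ploidy = c(2L, 4L),
                         mu = c(5e-9, 1e-8, 5e-8, 1e-7),
                         rho = c(1e-10, 1e-8, 1e-7),
                         s = c(-0.0005, -0.001, -0.005, -0.02, -0.1, -0.2),
                         replicates = 10L, generations = 10000L, L = 1e6,
                         base_seed = 1L,
                         aggregation_generation = generations,
                         selfing_allowed = TRUE,
                         pod_window = 1000L, pod_freq_threshold = 0.2,
                         pod_stability_threshold = 0.25) {
  for (nm in c("N", "ploidy", "mu", "rho", "s"))
    if (length(get(nm)) == 0L)
      stop("sweep parameter list '", nm, "' is empty", call. = FALSE)
  replicates <- as.integer(replicates)
  generations <- as.integer(generations)
  aggregation_generation <- as.integer(aggregation_generation)
  stopifnot(replicates >= 1L, generations >= 1L,
            aggregation_generation >= 1L,
            aggregation_generation <= generations)
  structure(list(N = as.integer(N), ploidy = as.integer(ploidy),
                 mu = as.numeric(mu), rho = as.numeric(rho),
                 s = as.numeric(s), replicates = replicates,
                 generations = generations, L = as.numeric(L),
                 base_seed = as.integer(base_seed),
                 aggregation_generation = aggregation_generation,
                 selfing_allowed = isTRUE(selfing_allowed),
                 pod_window = as.integer(pod_window),
                 pod_freq_threshold = pod_freq_threshold,
                 pod_stability_threshold = pod_stability_threshold),
            class = "pod_sweep_config")
}

#' @export
print.pod_sweep_config <- function(x, ...) {
  combos <- length(x$N) * length(x$ploidy) * length(x$mu) *
    length(x$rho) * length(x$s)
  cat("pod_sweep_config:\n")
  cat(sprintf("  %d combinations x %d replicates = %d runs of %d generations\n",
              combos, x$replicates, combos * x$replicates, x$generations))
  cat("  N:", paste(x$N, collapse = ", "), "\n")
  cat("  ploidy:", paste(x$ploidy, collapse = ", "), "\n")
  cat("  mu:", paste(format(x$mu), collapse = ", "), "\n")
  cat("  rho:", paste(format(x$rho), collapse = ", "), "\n")
  cat("  s:", paste(format(x$s), collapse = ", "), "\n")
  invisible(x)
}

## distinct reproducible seed per (combination, replicate); kept < 2^31
derive_seed <- function(base_seed, combo, replicate) {
  as.integer((as.double(base_seed) + 10007 * as.double(combo) +
                as.double(replicate)) %% 2147483647)
}

#' Expand a sweep configuration into per-run parameter sets
#'
#' Cartesian product of the parameter lists crossed with replicate
#' indices; every run receives a distinct seed derived deterministically
#' from `base_seed`, the combination index and the replicate index, so the
#' same configuration always yields the same seed assignment and results
#' are independent of execution order.
#'
#' @param config A [sweep_config()].
#' @return A data frame with one row per run: `combo`, `replicate`, `N`,
#'   `ploidy`, `mu`, `rho`, `s`, `generations`, `L`, `seed`.
#' @export
expand_sweep <- function(config) {
  stopifnot(inherits(config, "pod_sweep_config"))
  grid <- expand.grid(N = config$N, ploidy = config$ploidy, mu = config$mu,
                      rho = config$rho, s = config$s,
                      KEEP.OUT.ATTRS = FALSE)
  grid$combo <- seq_len(nrow(grid))
  runs <- merge(grid, data.frame(replicate = seq_len(config$replicates)))
  runs <- runs[order(runs$combo, runs$replicate), ]
  runs$generations <- config$generations
  runs$L <- config$L
  runs$seed <- derive_seed(config$base_seed, runs$combo, runs$replicate)
  rownames(runs) <- NULL
  runs[, c("combo", "replicate", "N", "ploidy", "mu", "rho", "s",
           "generations", "L", "seed")]
}

sweep_row_names <- c("combo", "replicate", "N", "ploidy", "mu", "rho", "s",
                     "generations", "L", "seed", "final_median_freq",
                     "final_mean_fitness", "is_pod", "window_mean",
                     "window_sd", "trajectory_file", "error")

#' Execute a parameter sweep
#'
#' Runs [wf_run()] for every row of [expand_sweep()] and collects one
#' result row per run: the median segregating allele frequency and mean
#' population fitness at the aggregation generation, plus the
#' [classify_pod()] call on the trajectory.  Per-run failures are recorded
#' in the `error` column rather than aborting the sweep.  When `out_dir`
#' is given, results are appended to `out_dir/sweep_results.tsv` as each
#' run finishes and full trajectories are written next to it, so an
#' interrupted sweep can `resume = TRUE` (completed seeds are skipped).
#' Because each run is isolated by its own seed, results are invariant to
#' execution order.
#'
#' @param config A [sweep_config()].
#' @param out_dir Optional directory for incremental results and per-run
#'   trajectory files.
#' @param resume If `TRUE`, skip runs whose results already exist in
#'   `out_dir/sweep_results.tsv`.
#' @param progress If `TRUE`, report each run on completion.
#' @return Data frame of result rows (one per combination x replicate).
#' @export
run_sweep <- function(config, out_dir = NULL, resume = FALSE,
                      progress = FALSE) {
  stopifnot(inherits(config, "pod_sweep_config"))
  runs <- expand_sweep(config)
  results_path <- NULL
  done <- data.frame()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    results_path <- file.path(out_dir, "sweep_results.tsv")
    if (resume && file.exists(results_path)) {
      done <- read.table(results_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    } else if (file.exists(results_path)) {
      file.remove(results_path)
    }
  }
  window <- min(config$pod_window, config$generations)
  rows <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    run <- runs[k, ]
    if (nrow(done) && any(done$seed == run$seed)) {
      rows[[k]] <- done[done$seed == run$seed, sweep_row_names][1, ]
      next
    }
    row <- run
    row$final_median_freq <- NA_real_
    row$final_mean_fitness <- NA_real_
    row$is_pod <- NA
    row$window_mean <- NA_real_
    row$window_sd <- NA_real_
    row$trajectory_file <- NA_character_
    row$error <- NA_character_
    res <- tryCatch({
      params <- sim_params(N = run$N, ploidy = run$ploidy, mu = run$mu,
                           rho = run$rho, s = run$s,
                           generations = run$generations, L = run$L,
                           seed = run$seed,
                           selfing_allowed = config$selfing_allowed)
      sim <- wf_run(params)
      at <- config$aggregation_generation
      row$final_median_freq <- sim$trajectory$median_allele_freq[at]
      row$final_mean_fitness <- sim$trajectory$mean_pop_fitness[at]
      call <- classify_pod(sim, window_length = window,
                           freq_threshold = config$pod_freq_threshold,
                           stability_threshold = config$pod_stability_threshold)
      row$is_pod <- call$is_pod
      row$window_mean <- call$window_mean
      row$window_sd <- call$window_sd
      if (!is.null(out_dir)) {
        tf <- file.path(out_dir, sprintf("traj_c%04d_r%02d.tsv",
                                         run$combo, run$replicate))
        write_stats(sim, tf)
        row$trajectory_file <- basename(tf)
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[k]] <- res[, sweep_row_names]
    if (!is.null(results_path)) {
      write.table(rows[[k]], results_path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = !file.exists(results_path),
                  append = file.exists(results_path))
    }
    if (progress)
      message(sprintf("[%d/%d] combo %d rep %d done", k, nrow(runs),
                      run$combo, run$replicate))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate sweep results per parameter combination
#'
#' Long-format per-combination mean, standard deviation and replicate
#' count of one result column -- the table behind median-allele-frequency
#' heatmaps and fitness-versus-recombination curves.  Rows with a missing
#' value (failed runs) are excluded and reflected in the count, with a
#' `complete` flag marking combinations that kept all replicates.
#'
#' @param rows Result data frame from [run_sweep()].
#' @param group_keys Parameter columns to group by.
#' @param value_key Result column to aggregate.
#' @return Data frame with the group keys, `mean`, `sd`, `n`, `complete`.
#' @export
aggregate_sweep <- function(rows, group_keys = c("N", "ploidy", "mu",
                                                 "rho", "s"),
                            value_key = "final_median_freq") {
  missing_keys <- setdiff(c(group_keys, value_key), names(rows))
  if (length(missing_keys))
    stop("unknown column(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  total <- aggregate(rows[[value_key]], rows[group_keys],
                     FUN = length)
  names(total)[ncol(total)] <- "n_total"
  ok <- !is.na(rows[[value_key]])
  agg <- aggregate(rows[[value_key]][ok], rows[ok, group_keys, drop = FALSE],
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- cbind(agg[group_keys], as.data.frame(agg$x))
  out <- merge(out, total, by = group_keys, all = TRUE)
  out$n[is.na(out$n)] <- 0
  out$complete <- out$n == out$n_total
  out$n_total <- NULL
  out
}
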