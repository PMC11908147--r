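## Summary statistics, pseudo-overdominance classification, and the exact
## two-haplotype genotype/gamete expectations under disomic and tetrasomic
## inheritance.

#' Frequencies of all segregating mutations
#'
#' @param population A `pod_population`.
#' @return Numeric vector of frequencies in `(0, 1)`, named by mutation
#'   id, for every mutation present on at least one but not all
#'   haplotypes.
#' @export
segregating_frequencies <- function(population) {
  counts <- carrier_counts(population)
  total <- population$ploidy * population$N
  counts <- counts[counts < total]
  counts / total
}

#' Median segregating allele frequency
#'
#' The median frequency over all segregating deleterious mutations; an
#' intermediate, stable value of this statistic at equilibrium is the
#' proxy used to diagnose pseudo-overdominance.  Returns 0 when nothing
#' segregates (convention for the mutation-free state).
#'
#' @param population A `pod_population`.
#' @return A value in `[0, 1]`.
#' @export
median_allele_frequency <- function(population) {
  f <- segregating_frequencies(population)
  if (length(f) == 0L) return(0)
  median(f)
}

#' Fitness of a virtual offspring cohort
#'
#' Generates `n_offspring` offspring from the current population by the
#' standard reproduction rules (fitness-proportional parents, one gamete
#' each) *without* replacing the population, and returns their fitness
#' values -- the input to offspring-fitness density plots and bimodality
#' checks.  Under pseudo-overdominance the distribution is bimodal:
#' near-zero-fitness homozygotes versus high-fitness heterozygotes.
#'
#' @param population A `pod_population`.
#' @param params A [sim_params()] object supplying `mu`, `rho`, `s` and
#'   `selfing_allowed`.
#' @param n_offspring Cohort size (default: the population size).
#' @return Numeric vector of `n_offspring` fitness values.
#' @export
offspring_fitness_snapshot <- function(population, params,
                                       n_offspring = population$N) {
  stopifnot(inherits(population, "pod_population"),
            inherits(params, "pod_params"))
  n_offspring <- as.integer(n_offspring)
  if (n_offspring < 0L) stop("'n_offspring' must be >= 0", call. = FALSE)
  if (n_offspring == 0L) return(numeric(0))
  reg <- population$registry
  engine_offspring(population$haplotypes, reg$pos, reg$s, reg$origin,
                   population$N, population$ploidy, population$L,
                   params$mu, params$rho, params$s, n_offspring,
                   params$selfing_allowed, population$generation)
}

#' Expected fully homozygous offspring fraction at a two-haplotype locus
#'
#' Under random union of `ploidy` independent copies (tetrasomic
#' Hardy-Weinberg composition) with focal-haplotype frequency `p`, the
#' probability that an offspring is fully homozygous for either haplotype
#' is `p^ploidy + (1-p)^ploidy`.  At `p = 0.4` this gives 52% of diploid
#' but only ~16% of tetraploid offspring -- the masking arithmetic that
#' favours pseudo-overdominance in autotetraploids.
#'
#' @param p Focal haplotype frequency (vectorized), in `[0, 1]`.
#' @param ploidy Number of chromosome copies (2, 4, or any positive
#'   integer for higher ploidies).
#' @return Probability in `[0, 1]`.
#' @examples
#' expected_homozygote_fraction(0.4, 2)  # 0.52
#' expected_homozygote_fraction(0.4, 4)  # 0.1552
#' @export
expected_homozygote_fraction <- function(p, ploidy) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  stopifnot(length(ploidy) == 1, ploidy >= 1)
  p^ploidy + (1 - p)^ploidy
}

#' Exact gamete distribution at a two-haplotype locus
#'
#' For a tetraploid parent carrying `copies_of_focal` copies of the focal
#' haplotype, enumerates the 3 equally likely bivalent matchings and the 2
#' chromatid choices per bivalent to give the exact distribution of the
#' number of focal copies (0, 1 or 2) in a gamete.  For diploids the
#' gamete carries one chromosome and the distribution is the trivial
#' single-draw law.
#'
#' Classic tetrasomic results recovered exactly: a triplex (AAAa) parent
#' transmits \{1: 1/2, 2: 1/2\}; a duplex (AAaa) parent \{0: 1/6, 1: 2/3,
#' 2: 1/6\}.
#'
#' @param copies_of_focal Integer in `0:ploidy`.
#' @param ploidy 2 or 4.
#' @return Named numeric vector over gamete focal-copy counts
#'   (`0:(ploidy/2)`), summing to 1.
#' @examples
#' bivalent_gamete_distribution(3)       # AAAa
#' bivalent_gamete_distribution(2)       # AAaa
#' @export
bivalent_gamete_distribution <- function(copies_of_focal, ploidy = 4) {
  stopifnot(length(copies_of_focal) == 1, ploidy %in% c(2, 4))
  copies_of_focal <- as.integer(copies_of_focal)
  if (is.na(copies_of_focal) || copies_of_focal < 0L ||
      copies_of_focal > ploidy)
    stop("'copies_of_focal' must lie in 0:ploidy", call. = FALSE)
  if (ploidy == 2) {
    pr <- c(`0` = 1 - copies_of_focal / 2, `1` = copies_of_focal / 2)
    return(pr)
  }
  is_focal <- c(rep(1L, copies_of_focal), rep(0L, 4L - copies_of_focal))
  pr <- c(`0` = 0, `1` = 0, `2` = 0)
  for (matching in bivalent_matchings) {      # 3 matchings, p = 1/3
    for (c1 in 1:2) {                         # chromatid coin, bivalent 1
      for (c2 in 1:2) {                       # chromatid coin, bivalent 2
        k <- is_focal[matching[[1L]][c1]] + is_focal[matching[[2L]][c2]]
        pr[k + 1L] <- pr[k + 1L] + 1 / 12
      }
    }
  }
  pr
}

#' Probability of fully focal-homozygous offspring from a cross
#'
#' For two parents described by their focal-haplotype copy counts at a
#' two-haplotype locus, returns the probability that an offspring is fully
#' homozygous for the focal (e.g. high-load) haplotype: both gametes must
#' carry the maximal number of focal copies.  Gamete laws come from
#' [bivalent_gamete_distribution()], i.e. strictly bivalent tetrasomic
#' meiosis for tetraploids.  The tetraploid maximum over heterozygous
#' parents is 25%, attained by AAAa x AAAa; the diploid Aa x Aa cross
#' gives 25% for the focal haplotype (so 50% counting either haplotype).
#'
#' @param copies1,copies2 Focal copy counts of the two parents, each in
#'   `0:ploidy`.
#' @param ploidy 2 or 4 (shared by both parents).
#' @return Probability in `[0, 1]`.
#' @examples
#' cross_high_load_fraction(3, 3)            # AAAa x AAAa: 0.25
#' cross_high_load_fraction(2, 2)            # AAaa x AAaa: 1/36
#' cross_high_load_fraction(1, 1, ploidy = 2)  # Aa x Aa: 0.25
#' @export
cross_high_load_fraction <- function(copies1, copies2, ploidy = 4) {
  g1 <- bivalent_gamete_distribution(copies1, ploidy)
  g2 <- bivalent_gamete_distribution(copies2, ploidy)
  top <- as.character(ploidy / 2)
  unname(g1[top] * g2[top])
}

#' Classify pseudo-overdominance from an allele-frequency trajectory
#'
#' A population is called pseudo-overdominant when its median segregating
#' allele frequency is *intermediate and stable* at equilibrium: over the
#' final `window_length` generations the mean of the per-generation median
#' allele frequency must reach `freq_threshold`, and its standard
#' deviation must not exceed `stability_threshold * mean` (high-variance
#' excursions to intermediate frequencies are drift, not
#' pseudo-overdominance).  Defaults sit between the observed regimes:
#' pseudo-overdominant runs equilibrate near 30-40% median frequency,
#' non-pseudo-overdominant runs near 0-10%.
#'
#' @param trajectory A `pod_sim` object or a trajectory data frame with a
#'   `median_allele_freq` column (and optionally `generation`).
#' @param window_length Number of final generations to assess (default
#'   1000); the trajectory must be at least this long.
#' @param freq_threshold Minimum window mean of the median allele
#'   frequency (default 0.2).
#' @param stability_threshold Maximum allowed coefficient of variation
#'   (sd/mean) within the window (default 0.25).
#' @return An object of class `pod_call`: list with `is_pod`,
#'   `window_mean`, `window_sd`, `window` (generation range) and the
#'   thresholds used.
#' @examples
#' tr <- data.frame(generation = 1:2000,
#'                  median_allele_freq = rep(0.35, 2000))
#' classify_pod(tr)
#' @export
classify_pod <- function(trajectory, window_length = 1000L,
                         freq_threshold = 0.2, stability_threshold = 0.25) {
  if (inherits(trajectory, "pod_sim")) trajectory <- trajectory$trajectory
  if (!is.data.frame(trajectory) ||
      !"median_allele_freq" %in% names(trajectory))
    stop("'trajectory' must be a pod_sim or a data frame with a ",
         "'median_allele_freq' column", call. = FALSE)
  window_length <- as.integer(window_length)
  if (window_length < 2L || nrow(trajectory) < window_length)
    stop("trajectory must be at least as long as 'window_length' (>= 2)",
         call. = FALSE)
  win <- tail(trajectory, window_length)
  m <- mean(win$median_allele_freq)
  sdev <- sd(win$median_allele_freq)
  gens <- if ("generation" %in% names(win)) range(win$generation)
          else c(nrow(trajectory) - window_length + 1L, nrow(trajectory))
  is_pod <- (m >= freq_threshold) &&
    (sdev <= stability_threshold * m)
  structure(list(is_pod = is_pod, window_mean = m, window_sd = sdev,
                 window = as.integer(gens), freq_threshold = freq_threshold,
                 stability_threshold = stability_threshold),
            class = "pod_call")
}

#' @export
print.pod_call <- function(x, ...) {
  cat(sprintf("pseudo-overdominance call: %s\n",
              if (x$is_pod) "POD" else "not POD"))
  cat(sprintf("  window: generations %d-%d\n", x$window[1], x$window[2]))
  cat(sprintf("  median allele frequency: mean %.4f (threshold >= %.2f), sd %.4f (threshold <= %.2f x mean)\n",
              x$window_mean, x$freq_threshold, x$window_sd,
              x$stability_threshold))
  invisible(x)
}
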