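test_that("crossover plans follow the Poisson(rho * L) law", {
  expect_error(draw_crossovers(-1e-8, 1e6), "non-negative")

  # rho = 0: never any breakpoint
  set.seed(1)
  for (i in 1:50) {
    plan <- draw_crossovers(0, 1e6)
    expect_length(plan$breakpoints, 0)
    expect_true(plan$start_copy %in% c(1L, 2L))
  }

  # breakpoints are strictly increasing boundaries within (0, L)
  set.seed(2)
  for (i in 1:50) {
    plan <- draw_crossovers(5e-6, 1e6)
    bp <- plan$breakpoints
    if (length(bp) > 1) expect_true(all(diff(bp) > 0))
    if (length(bp) > 0) expect_true(all(bp >= 1 & bp <= 1e6 - 1))
  }

  # mean crossover count ~ rho * L (duplicate boundary hits are measure
  # ~0 at L = 1e6, so cancellation does not bias the mean)
  set.seed(3)
  n <- 20000
  counts <- vapply(seq_len(n), function(i)
    length(draw_crossovers(1e-6, 1e6)$breakpoints), integer(1))
  expect_equal(mean(counts), 1, tolerance = 3 / sqrt(n))

  # goodness of fit against Poisson(1)
  tab <- tabulate(pmin(counts, 4L) + 1L, nbins = 5L)
  p_expect <- c(dpois(0:3, 1), ppois(3, 1, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(tab, p = p_expect))
  expect_gt(gof$p.value, 0.001)
})

test_that("recombination copies interval contents without loss or invention", {
  reg <- new_registry()
  id1 <- register_mutations(reg, pos = 100, s = -0.01)
  id2 <- register_mutations(reg, pos = 900, s = -0.01)
  plan <- structure(list(breakpoints = 500L, start_copy = 1L),
                    class = "crossover_plan")

  # hand enumeration: left of 500 from A, right of 500 from B
  expect_identical(recombine(id1, id2, plan, reg), c(id1, id2))
  # starting on B picks neither mutation
  plan$start_copy <- 2L
  expect_identical(recombine(id1, id2, plan, reg), integer(0))

  # no breakpoints: exact copy of the start template
  empty_plan <- structure(list(breakpoints = integer(0), start_copy = 1L),
                          class = "crossover_plan")
  expect_identical(recombine(id1, id2, empty_plan, reg), id1)

  # identical templates: output equals the template for any plan
  set.seed(4)
  ids <- register_mutations(reg, pos = sort(runif(20) * 1e6), s = -0.01)
  for (i in 1:20) {
    plan <- draw_crossovers(5e-6, 1e6)
    expect_identical(recombine(ids, ids, plan, reg), ids)
  }

  # property: the recombinant at each position matches the template that
  # owns that segment
  set.seed(5)
  for (i in 1:20) {
    hapA <- sort(sample(ids, 8))
    hapB <- sort(sample(ids, 8))
    plan <- draw_crossovers(5e-6, 1e6)
    out <- recombine(hapA, hapB, plan, reg)
    seg_of <- function(p) findInterval(p, plan$breakpoints)
    from_A <- (seg_of(reg$pos[hapA]) %% 2 == 0) == (plan$start_copy == 1)
    from_B <- (seg_of(reg$pos[hapB]) %% 2 == 0) == (plan$start_copy == 2)
    expect_setequal(out, c(hapA[from_A], hapB[from_B]))
  }
})

test_that("all three bivalent matchings are equally likely", {
  set.seed(6)
  n <- 6000
  keys <- vapply(seq_len(n), function(i) {
    pairing <- pair_bivalents()
    # every draw is a perfect matching of 1:4
    expect_setequal(unlist(pairing), 1:4)
    paste(sort(vapply(pairing, function(p) paste(sort(p), collapse = ""),
                      character(1))), collapse = "|")
  }, character(1))
  freq <- table(keys) / n
  expect_length(freq, 3)
  expect_equal(as.numeric(freq), rep(1 / 3, 3),
               tolerance = 4 * sqrt((1 / 3) * (2 / 3) / n) / (1 / 3))
})

test_that("gametes carry one chromosome per bivalent and mutate at rate mu * L", {
  pop <- two_hap_population(2, ploidy = 4)
  parent <- individual_copies(pop, 1)

  params0 <- sim_params(N = 2, ploidy = 4, mu = 0, rho = 0, s = -0.005,
                        generations = 1)
  set.seed(7)
  for (i in 1:20) {
    gam <- make_gamete(parent, params0, pop$registry)
    expect_length(gam, 2)   # tetraploid gamete: exactly two chromosomes
    # with rho = 0 and mu = 0 every gamete chromosome is a parental copy
    for (h in gam)
      expect_true(any(vapply(parent, identical, logical(1), y = h)))
  }

  # diploid gametes carry exactly one chromosome
  pop2 <- two_hap_population(1, ploidy = 2)
  params2 <- sim_params(N = 2, ploidy = 2, mu = 0, rho = 0, s = -0.005,
                        generations = 1)
  gam2 <- make_gamete(individual_copies(pop2, 1), params2, pop2$registry)
  expect_length(gam2, 1)
  expect_error(make_gamete(individual_copies(pop2, 1), params0,
                           pop2$registry), "ploidy")

  # mu > 0: Poisson(mu * L) fresh, distinct ids per gamete chromosome
  params_mu <- sim_params(N = 2, ploidy = 4, mu = 1e-5, rho = 0, s = -0.005,
                          generations = 1)
  set.seed(8)
  n_before <- length(pop$registry$pos)
  seen <- integer(0)
  n_new <- vapply(1:500, function(i) {
    gam <- make_gamete(parent, params_mu, pop$registry)
    new_ids <- unlist(lapply(gam, function(h) h[h > n_before]))
    seen <<- c(seen, new_ids)
    length(new_ids)
  }, numeric(1))
  expect_equal(mean(n_new) / 2, 10, tolerance = 0.1)  # mu * L = 10 per chromosome
  expect_identical(anyDuplicated(seen), 0L)           # ids are never reused
})

test_that("empirical gamete laws match the bivalent enumeration oracle", {
  set.seed(9)
  n <- 20000
  # triplex AAAa: {1: 1/2, 2: 1/2}; duplex AAaa: {0: 1/6, 1: 2/3, 2: 1/6}
  for (k in c(3L, 2L)) {
    emp <- sample_gamete_law(k, ploidy = 4, n_draws = n)
    oracle <- enumerate_gamete_law(k)
    expect_equal(as.numeric(emp), as.numeric(oracle),
                 tolerance = 4 * sqrt(0.25 / n) / min(oracle[oracle > 0]))
  }
  # diploid heterozygote transmits each copy with probability 1/2
  emp2 <- sample_gamete_law(1L, ploidy = 2, n_draws = 10000)
  expect_equal(as.numeric(emp2), c(0.5, 0.5), tolerance = 0.05)
})
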