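test_that("simulation parameters are validated", {
  ok <- function(...) sim_params(N = 100, ploidy = 2, mu = 1e-7, rho = 1e-8,
                                 s = -0.005, generations = 10, ...)
  expect_s3_class(ok(), "pod_params")
  expect_error(sim_params(N = 1, ploidy = 2, mu = 0, rho = 0, s = 0,
                          generations = 1), "N")
  expect_error(sim_params(N = 10, ploidy = 3, mu = 0, rho = 0, s = 0,
                          generations = 1), "ploidy")
  expect_error(sim_params(N = 10, ploidy = 2, mu = -1e-8, rho = 0, s = 0,
                          generations = 1), "mu")
  expect_error(sim_params(N = 10, ploidy = 2, mu = 0, rho = 0, s = 0.5,
                          generations = 1), "\\(-1, 0\\]")
  expect_error(sim_params(N = 10, ploidy = 2, mu = 0, rho = 0, s = -1,
                          generations = 1), "\\(-1, 0\\]")
  expect_error(ok(snapshot_generations = 99), "1:generations")
})

test_that("parent choice is fitness-proportional", {
  # two individuals with fitness 0.5 and 1.0: probabilities 1/3 and 2/3
  muts <- data.frame(pos = 100, s = -0.5)
  pop <- fixture_population(list(1L, 1L, integer(0), integer(0)), muts,
                            ploidy = 2)
  expect_equal(population_fitness(pop), c(0.5, 1))
  set.seed(10)
  draws <- select_parent(pop, 30000)
  expect_equal(mean(draws == 1), 1 / 3, tolerance = 0.02)

  # equal fitness: uniform choice
  unif <- new_population(4, 2)
  set.seed(11)
  expect_equal(as.numeric(table(select_parent(unif, 40000)) / 40000),
               rep(0.25, 4), tolerance = 0.05)
})

test_that("a generation step conserves N and ploidy and indexes generations", {
  params <- sim_params(N = 30, ploidy = 4, mu = 1e-7, rho = 1e-8, s = -0.1,
                       generations = 1)
  pop <- new_population(30, 4)
  set.seed(12)
  for (g in 1:5) {
    out <- wf_step(pop, params)
    pop <- out$population
    expect_identical(pop$generation, g)
    expect_identical(out$stats$generation, g)
    expect_length(pop$haplotypes, 30L * 4L)
    expect_identical(pop$N, 30L)
  }
  # stats invariants
  expect_true(out$stats$mean_pop_fitness > 0 &&
                out$stats$mean_pop_fitness <= 1)
  expect_true(out$stats$median_allele_freq >= 0 &&
                out$stats$median_allele_freq < 1)
})

test_that("a monomorphic neutral population stays monomorphic at fitness one", {
  params <- sim_params(N = 20, ploidy = 2, mu = 0, rho = 0, s = 0,
                       generations = 50, seed = 13)
  sim <- wf_run(params)
  expect_true(all(sim$trajectory$mean_pop_fitness == 1))
  expect_true(all(sim$trajectory$n_segregating == 0L))
  expect_true(all(sim$trajectory$median_allele_freq == 0))
  expect_true(all(sim$trajectory$mean_parent_fitness == 1))
})

test_that("runs are seed-deterministic and leave the session RNG alone", {
  params <- sim_params(N = 30, ploidy = 4, mu = 1e-7, rho = 1e-8, s = -0.01,
                       generations = 60, seed = 14,
                       snapshot_generations = c(30L, 60L))
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  sim1 <- wf_run(params)
  # session RNG stream unaffected by the seeded run
  expect_identical(runif(1), before)
  sim2 <- wf_run(params)
  expect_identical(sim1$trajectory, sim2$trajectory)
  expect_identical(sim1$population$haplotypes, sim2$population$haplotypes)
  expect_identical(sim1$snapshots, sim2$snapshots)
  expect_identical(nrow(sim1$trajectory), 60L)
  expect_named(sim1$snapshots, c("30", "60"))

  # generations = 1 gives a length-1 trajectory
  one <- wf_run(sim_params(N = 10, ploidy = 2, mu = 0, rho = 0, s = 0,
                           generations = 1, seed = 1))
  expect_identical(nrow(one$trajectory), 1L)
})

test_that("the engine's fitness agrees with the reference R implementation", {
  params <- sim_params(N = 25, ploidy = 4, mu = 5e-7, rho = 1e-8, s = -0.05,
                       generations = 40, seed = 15,
                       snapshot_generations = 40L)
  sim <- wf_run(params)
  w_r <- population_fitness(sim$population)
  # snapshot at the final generation is the final cohort's fitness vector
  expect_equal(sim$snapshots[["40"]], w_r)
  expect_equal(sim$trajectory$mean_pop_fitness[40], mean(w_r))
  expect_equal(sim$trajectory$sd_pop_fitness[40], sd(w_r))
  # median allele frequency recomputed by the R stats route
  expect_equal(sim$trajectory$median_allele_freq[40],
               median_allele_frequency(sim$population))
  expect_identical(sim$trajectory$n_segregating[40],
                   length(segregating_frequencies(sim$population)))
})

test_that("a neutral allele frequency is a martingale across one generation", {
  p0 <- 0.3
  N <- 50
  pop <- fixture_population(
    c(rep(list(1L), p0 * 2 * N), rep(list(integer(0)), (1 - p0) * 2 * N)),
    data.frame(pos = 100, s = 0), ploidy = 2)
  params <- sim_params(N = N, ploidy = 2, mu = 0, rho = 0, s = 0,
                       generations = 1)
  set.seed(16)
  reps <- 400
  freqs <- vapply(seq_len(reps), function(i) {
    out <- wf_step(pop, params)
    f <- out$stats$median_allele_freq      # single segregating mutation
    if (out$stats$n_segregating == 0L)     # absorbed: fixed or lost
      f <- ifelse(out$stats$n_substitutions > 0, 1, 0)
    f
  }, numeric(1))
  se <- sqrt(p0 * (1 - p0) / (2 * N) / reps)
  expect_lt(abs(mean(freqs) - p0), 3 * se)
})

test_that("a single neutral copy fixes with probability 1 / (ploidy * N)", {
  # diploid N = 10: fixation probability 1/20
  N <- 10
  reps <- 1500
  pop <- fixture_population(
    c(list(1L), rep(list(integer(0)), 2 * N - 1)),
    data.frame(pos = 100, s = 0), ploidy = 2)
  params <- sim_params(N = N, ploidy = 2, mu = 0, rho = 0, s = 0,
                       generations = 300)
  set.seed(17)
  fixed <- vapply(seq_len(reps), function(i) {
    sim <- wf_run(params, population = pop)
    last <- sim$trajectory[nrow(sim$trajectory), ]
    expect_identical(last$n_segregating, 0L)  # absorbed well before 300 gens
    last$n_substitutions > 0L
  }, logical(1))
  p_fix <- 1 / (2 * N)
  se <- sqrt(p_fix * (1 - p_fix) / reps)
  expect_lt(abs(mean(fixed) - p_fix), 3 * se)
})

test_that("selfing can be excluded", {
  # with N = 2, no selfing and distinguishable parents, every offspring
  # must inherit material from both individuals
  muts <- data.frame(pos = c(100, 900), s = 0)
  pop <- fixture_population(list(1L, 1L, 2L, 2L), muts, ploidy = 2)
  params <- sim_params(N = 2, ploidy = 2, mu = 0, rho = 0, s = 0,
                       generations = 1, selfing_allowed = FALSE)
  set.seed(18)
  for (i in 1:20) {
    out <- wf_step(pop, params)
    for (ind in 1:2) {
      copies <- individual_copies(out$population, ind)
      carried <- sort(unique(unlist(copies)))
      expect_identical(carried, c(1L, 2L))  # one copy from each parent
    }
  }
})
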