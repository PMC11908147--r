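test_that("median allele frequency summarizes segregating mutations only", {
  muts <- data.frame(pos = c(100, 500, 900), s = -0.01)
  # frequencies 0.1, 0.3, 0.5 over 10 diploid copies (N = 5)
  copies <- list(c(1L, 2L, 3L), c(2L, 3L), c(2L, 3L), 3L, 3L,
                 integer(0), integer(0), integer(0), integer(0),
                 integer(0))
  pop <- fixture_population(copies, muts, ploidy = 2)
  expect_equal(unname(segregating_frequencies(pop)), c(0.1, 0.3, 0.5))
  expect_equal(median_allele_frequency(pop), 0.3)

  # single mutation at 0.4
  pop1 <- fixture_population(c(rep(list(1L), 4), rep(list(integer(0)), 6)),
                             muts, ploidy = 2)
  expect_equal(median_allele_frequency(pop1), 0.4)

  # no segregating mutations: 0 by convention
  expect_equal(median_allele_frequency(new_population(5, 2)), 0)
})

test_that("homozygote fractions reproduce the diploid/tetraploid masking arithmetic", {
  # at p = 0.4: 52% of diploid offspring fully homozygous vs ~16% (15.52%)
  # of tetraploid offspring
  expect_equal(expected_homozygote_fraction(0.4, 2), 0.52)
  expect_equal(expected_homozygote_fraction(0.4, 4), 0.1552)
  expect_equal(round(100 * expected_homozygote_fraction(0.4, 4)), 16)
  # boundaries and symmetry
  expect_equal(expected_homozygote_fraction(1, 7), 1)
  expect_equal(expected_homozygote_fraction(0.5, 2), 0.5)
  expect_error(expected_homozygote_fraction(1.2, 2), "\\[0, 1\\]")

  # masking inequality: tetraploids always form fewer homozygotes
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(expected_homozygote_fraction(p, 4) <
                    expected_homozygote_fraction(p, 2)))
})

test_that("the bivalent gamete law matches exhaustive enumeration for all genotypes", {
  for (k in 0:4) {
    law <- bivalent_gamete_distribution(k)
    expect_equal(sum(law), 1)
    expect_equal(law, enumerate_gamete_law(k))
  }
  # classic tetrasomic segregation ratios, frozen
  expect_equal(bivalent_gamete_distribution(3),
               c(`0` = 0, `1` = 1 / 2, `2` = 1 / 2))
  expect_equal(bivalent_gamete_distribution(2),
               c(`0` = 1 / 6, `1` = 2 / 3, `2` = 1 / 6))
  expect_equal(bivalent_gamete_distribution(4), c(`0` = 0, `1` = 0, `2` = 1))
  expect_error(bivalent_gamete_distribution(5), "0:ploidy")
})

test_that("cross expectations give the 0-25% tetraploid high-load offspring range", {
  # maximum at AAAa x AAAa
  expect_equal(cross_high_load_fraction(3, 3), 0.25)
  expect_equal(cross_high_load_fraction(4, 4), 1)
  expect_equal(cross_high_load_fraction(2, 2), 1 / 36)
  expect_equal(cross_high_load_fraction(0, 4), 0)
  # diploid Aa x Aa: quarter for the focal haplotype, half for either
  expect_equal(cross_high_load_fraction(1, 1, ploidy = 2), 0.25)
  both <- cross_high_load_fraction(1, 1, ploidy = 2) +
    cross_high_load_fraction(2 - 1, 2 - 1, ploidy = 2)
  expect_equal(both, 0.5)
  # the tetraploid range over heterozygous parents is 0-25%: crosses
  # involving a simplex (Aaaa) parent give exactly 0 focal homozygotes
  fr <- outer(1:3, 1:3, Vectorize(cross_high_load_fraction))
  expect_equal(max(fr), 0.25)
  expect_true(all(fr >= 0 & fr <= 0.25))
  expect_equal(fr[1, ], rep(0, 3))
})

test_that("pseudo-overdominance calls require intermediate AND stable frequencies", {
  gens <- 1:2000
  flat <- data.frame(generation = gens, median_allele_freq = rep(0.35, 2000))
  call <- classify_pod(flat)
  expect_true(call$is_pod)
  expect_equal(call$window_mean, 0.35)
  expect_identical(call$window, c(1001L, 2000L))

  low <- data.frame(generation = gens,
                    median_allele_freq = runif(2000, 0, 0.04))
  expect_false(classify_pod(low)$is_pod)

  # oscillating between 0 and 0.45: intermediate mean but unstable
  swing <- data.frame(generation = gens,
                      median_allele_freq = rep(c(0, 0.45), 1000))
  call_swing <- classify_pod(swing)
  expect_false(call_swing$is_pod)
  expect_gt(call_swing$window_mean, 0.2)  # fails on stability, not level

  expect_error(classify_pod(flat[1:500, ]), "window_length")
})

test_that("offspring snapshots expose the homozygote classes of a cross", {
  params4 <- sim_params(N = 3, ploidy = 4, mu = 0, rho = 0, s = -0.5,
                        generations = 1)
  # all-duplex (AAaa) tetraploid population with complementary haplotypes:
  # offspring are fully homozygous for either haplotype w.p. 2 * (1/6)^2
  pop4 <- two_hap_population(c(2, 2, 2), ploidy = 4, s = -0.5)
  set.seed(19)
  w4 <- offspring_fitness_snapshot(pop4, params4, n_offspring = 20000)
  expect_true(all(w4 %in% c(0.5, 1)))     # bimodal: masked vs homozygous
  expect_equal(mean(w4 == 0.5), 2 / 36, tolerance = 0.15)

  # all-heterozygote diploid population: half the offspring homozygous
  pop2 <- two_hap_population(c(1, 1, 1), ploidy = 2, s = -0.5)
  params2 <- sim_params(N = 3, ploidy = 2, mu = 0, rho = 0, s = -0.5,
                        generations = 1)
  set.seed(20)
  w2 <- offspring_fitness_snapshot(pop2, params2, n_offspring = 20000)
  expect_equal(mean(w2 == 0.5), 0.5, tolerance = 0.02)

  # degenerate sizes and mutation-free populations
  expect_identical(offspring_fitness_snapshot(pop4, params4, 0), numeric(0))
  clean <- new_population(5, 4)
  expect_equal(offspring_fitness_snapshot(clean, params4, 50), rep(1, 50))
})
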