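# Shared fixtures and independent oracles for the test suite.

# Two-haplotype fixture: every individual carries `counts[i]` copies of the
# focal haplotype A (mutations `a_rows`) and the rest of the alternative
# haplotype a (mutations `b_rows`).  Mutation table: row 1.. = A mutations,
# then a mutations.
two_hap_population <- function(counts, ploidy, n_mut = 1L, s = -0.005,
                               L = 1e6) {
  stopifnot(all(counts >= 0), all(counts <= ploidy))
  a_pos <- seq(100, by = 10, length.out = n_mut)
  b_pos <- seq(5e5, by = 10, length.out = n_mut)
  muts <- data.frame(pos = c(a_pos, b_pos), s = s)
  a_rows <- seq_len(n_mut)
  b_rows <- n_mut + seq_len(n_mut)
  copies <- unlist(lapply(counts, function(k)
    c(rep(list(a_rows), k), rep(list(b_rows), ploidy - k))),
    recursive = FALSE)
  fixture_population(copies, muts, ploidy = ploidy, L = L)
}

# Independent brute-force oracle for the tetraploid gamete law: enumerate
# the three bivalent matchings (generated from partner choices of copy 1,
# not the package's matching table) and the two chromatid coins per
# bivalent; all 12 outcomes equally likely.
enumerate_gamete_law <- function(copies_of_focal) {
  is_focal <- c(rep(1L, copies_of_focal), rep(0L, 4L - copies_of_focal))
  pr <- c(`0` = 0, `1` = 0, `2` = 0)
  for (partner in 2:4) {
    b1 <- c(1L, partner)
    b2 <- setdiff(2:4, partner)
    for (c1 in 1:2) for (c2 in 1:2) {
      k <- is_focal[b1[c1]] + is_focal[b2[c2]]
      pr[k + 1L] <- pr[k + 1L] + 1 / 12
    }
  }
  pr
}

# Empirical gamete focal-copy-count distribution using the R-level meiosis
# operations on a two-haplotype parent (focal haplotype = mutation row 1).
sample_gamete_law <- function(copies_of_focal, ploidy, n_draws,
                              rho = 0, mu = 0) {
  pop <- two_hap_population(copies_of_focal, ploidy = ploidy)
  parent <- individual_copies(pop, 1L)
  params <- sim_params(N = 2, ploidy = ploidy, mu = mu, rho = rho, s = -0.005,
                       generations = 1)
  focal_id <- 1L
  draws <- vapply(seq_len(n_draws), function(i) {
    gam <- make_gamete(parent, params, pop$registry)
    sum(vapply(gam, function(h) focal_id %in% h, logical(1)))
  }, integer(1))
  tabulate(draws + 1L, nbins = ploidy / 2 + 1L) / n_draws
}
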