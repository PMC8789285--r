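test_that("the zygote inbreeding estimator follows 1 - observed/expected", {
  # observed heterozygosity equal to Hardy-Weinberg expectation
  expect_equal(inbreeding_from_zygotes(zygote_counts(25, 50, 25, 0.5)), 0)
  # no heterozygous mated cells at all: exclusive like-with-like mating
  expect_equal(inbreeding_from_zygotes(zygote_counts(12, 0, 30, 0.3)), 1)
  # half the expected heterozygosity
  expect_equal(inbreeding_from_zygotes(zygote_counts(30, 10, 0, 0.5)), 0.5)
  # excess heterozygosity gives a negative coefficient
  expect_lt(inbreeding_from_zygotes(zygote_counts(10, 80, 10, 0.5)), 0)
  expect_error(inbreeding_from_zygotes(zygote_counts(0, 0, 0, 0.5)), "empty")
  expect_error(inbreeding_from_zygotes(zygote_counts(5, 5, 5, 0)), "undefined")
  # allele frequency re-estimated from the table itself
  expect_equal(inbreeding_from_zygotes(zygote_counts(25, 50, 25, 0.9),
                                       reestimate_p = TRUE), 0)
})

test_that("mating efficiency weights mated units and spores by cell equivalents", {
  expect_equal(mating_efficiency(V = 10, Z = 0, A = 0, S = 0), 0)
  expect_equal(mating_efficiency(V = 0, Z = 3, A = 1, S = 4), 100)
  expect_equal(mating_efficiency(V = 2, Z = 1, A = 1, S = 2), 500 / 9)
  # scale invariance
  expect_equal(mating_efficiency(20, 10, 10, 20),
               mating_efficiency(2, 1, 1, 2))
  # per-cell accounting via the configurable vegetative weight
  expect_equal(mating_efficiency(2, 1, 1, 2, vegetative_weight = 1),
               100 * 5 / 7)
  expect_error(mating_efficiency(0, 0, 0, 0), "empty")
})

test_that("recombinant correction divisors come from the 2^n genotype lattice", {
  # exhaustive enumeration: progeny of a multilocus heterozygote
  for (n in 2:3) {
    genos <- as.matrix(expand.grid(rep(list(c(1L, 2L)), n)))
    parental <- apply(genos, 1, function(g) all(g == 1L) || all(g == 2L))
    share <- mean(!parental)             # (2^n - 2) / 2^n
    expect_equal(share, (2^n - 2) / 2^n)
    # the estimator divides by exactly this share
    expect_equal(outcross_from_recombinants(share / 2, n), 0.5)
  }
  expect_equal(outcross_from_recombinants(0.375, 3), 0.5)
  expect_equal(outcross_from_recombinants(0.25, 2), 0.5)
  expect_warning(capped <- outcross_from_recombinants(0.9, 2), "capped")
  expect_equal(capped, 1)
  expect_error(outcross_from_recombinants(0.1, 1), "n_markers")
})

test_that("the genetic inbreeding estimator composes correction and F formula", {
  expect_equal(inbreeding_from_genetic(0, 3, 0.5), 1)
  expect_equal(inbreeding_from_genetic(0.375, 3, 0.5), 0)
  expect_equal(inbreeding_from_genetic(0.125, 2, 0.5), 0.5)
  expect_error(inbreeding_from_genetic(0.1, 2, 1), "strictly in")
})

test_that("mixed-cross expectations reduce correctly and stay on the simplex", {
  # symmetric full-mating limit recovers the plain genotype frequencies
  for (Fv in c(0, 0.4, 1)) {
    expect_equal(unname(expected_mixed_cross(0.5, Fv, Fv, 1, 1)),
                 unname(drop(genotype_freqs(0.5, Fv))))
  }
  # direct evaluation of the additive model
  expect_equal(unname(expected_mixed_cross(0.5, 0.5, 0, 0.4, 0.5)),
               c(0.15, 0.16875, 0.68125))
  # two fully inbreeding parents never form heterozygotes
  expect_equal(unname(expected_mixed_cross(0.5, 1, 1, 0.7, 0.2)["het"]), 0)
  # simplex by construction over a parameter grid
  set.seed(4)
  for (i in 1:50) {
    v <- runif(5)
    out <- expected_mixed_cross(v[1], v[2], v[3], v[4], v[5])
    expect_equal(sum(out), 1)
    expect_true(all(out >= 0))
  }
})

test_that("bootstrap intervals are reproducible and collapse on degenerate data", {
  counts <- zygote_counts(300, 100, 200, 0.5)
  ci1 <- bootstrap_ci(counts, n_boot = 300, seed = 10)
  ci2 <- bootstrap_ci(counts, n_boot = 300, seed = 10)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lt(ci1$lower, ci1$estimate)
  expect_gt(ci1$upper, ci1$estimate)
  # all mass in one homozygote class: the F estimate is pinned at 1
  ci3 <- bootstrap_ci(zygote_counts(500, 0, 0, 0.5), n_boot = 200, seed = 1)
  expect_equal(ci3$lower, 1)
  expect_equal(ci3$upper, 1)
  expect_error(bootstrap_ci(counts, n_boot = 0), "at least 100")
})

test_that("bootstrap intervals cover the generating F at the nominal rate", {
  hits <- 0L
  reps <- 120L
  for (i in seq_len(reps)) {
    counts <- sim_zygote_counts(0.5, 0.5, 10000, seed = 5000 + i)
    ci <- bootstrap_ci(counts, n_boot = 400, seed = 6000 + i)
    if (ci$lower <= 0.5 && ci$upper >= 0.5) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.88)
  expect_lte(hits / reps, 1)
})

test_that("microscopy and genetic estimators agree on data from one mating process", {
  for (Fv in c(0.2, 0.5)) {
    zyg <- sim_zygote_counts(0.5, Fv, 5000, seed = 31)
    prog <- sim_progeny_table(0.5, Fv, 3, 5000, seed = 32)
    F_zyg <- inbreeding_from_zygotes(zyg)
    F_gen <- inbreeding_from_genetic(recombinant_fraction(prog), 3, 0.5)
    expect_lt(abs(F_zyg - F_gen), 0.05)
  }
})
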