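test_that("zygote count draws respect the generating genotype law", {
  z0 <- sim_zygote_counts(0.5, 0.5, 0, seed = 1)
  expect_equal(z0$n_hom1 + z0$n_het + z0$n_hom2, 0L)
  # exclusive inbreeding never produces heterozygous zygotes
  for (s in 1:5) {
    z <- sim_zygote_counts(0.4, 1, 500, seed = s)
    expect_identical(z$n_het, 0L)
  }
  # random mating at p = 0.5: het fraction within 3 binomial SEs of 1/2
  z <- sim_zygote_counts(0.5, 0, 10000, seed = 9)
  het_frac <- z$n_het / 10000
  expect_lt(abs(het_frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("generators are deterministic under a seed and preserve RNG state", {
  set.seed(777)
  before <- .Random.seed
  a <- sim_zygote_counts(0.3, 0.5, 1000, seed = 2)
  expect_identical(.Random.seed, before)
  b <- sim_zygote_counts(0.3, 0.5, 1000, seed = 2)
  expect_identical(unclass(a)[1:3], unclass(b)[1:3])
  c1 <- sim_zygote_counts(0.3, 0.5, 1000, seed = 3)
  expect_false(identical(unclass(a)[1:3], unclass(c1)[1:3]))
  t1 <- sim_evolution_trajectories(0.5, G = 4, seed = 5)
  t2 <- sim_evolution_trajectories(0.5, G = 4, seed = 5)
  expect_identical(t1$freq, t2$freq)
})

test_that("progeny tables segregate unlinked markers through the mating law", {
  # exclusive inbreeding: no recombinant progeny at all
  prog <- sim_progeny_table(0.5, 1, 3, 2000, seed = 4)
  expect_equal(recombinant_fraction(prog), 0)
  # random mating at p = 0.5 with three markers: recombinant share
  # 2p(1-p) * (2^3 - 2)/2^3 = 0.375
  prog <- sim_progeny_table(0.5, 0, 3, 20000, seed = 6)
  rf <- recombinant_fraction(prog)
  expect_lt(abs(rf - 0.375), 3 * sqrt(0.375 * 0.625 / 20000))
  # round trip through the genetic estimator
  for (Fv in c(0, 0.5, 0.8)) {
    prog <- sim_progeny_table(0.5, Fv, 3, 20000, seed = 40 + round(10 * Fv))
    F_hat <- inbreeding_from_genetic(recombinant_fraction(prog), 3, 0.5)
    expect_lt(abs(F_hat - Fv), 0.03)
  }
  expect_error(sim_progeny_table(0.5, 0, 4, 10), "2 or 3")
})

test_that("neutral no-loss trajectories fluctuate around the start frequency", {
  d <- sim_evolution_trajectories(0.4, c = 0, k = 0.5, F = 0.3, G = 6,
                                  replicates = 3, effective_n = 10000,
                                  seed = 12)
  expect_equal(attr(d, "truth")$freq, rep(0.4, 7))
  expect_true(all(abs(d$freq - 0.4) < 5 * sqrt(0.4 * 0.6 / 10000)))
})

test_that("driven trajectories track the deterministic recursion", {
  d <- sim_evolution_trajectories(0.5, c = 0, k = 0.98, F = 0.5, G = 6,
                                  replicates = 3, seed = 13)
  pars <- drive_params(k = 0.98, w12 = het_drive_fitness(0.98), F = 0.5)
  expected <- drive_trajectory(0.5, pars, 6)$p
  expect_equal(attr(d, "truth")$freq, expected)
  for (r in 1:3) {
    obs <- d$freq[d$replicate == r][order(d$generation[d$replicate == r])]
    expect_true(all(abs(obs - expected) < 5 * sqrt(0.25 / 10000)))
  }
})

test_that("less inbreeding speeds the driver at every generation", {
  d0 <- sim_evolution_trajectories(0.5, k = 0.98, F = 0, G = 6, seed = 14)
  d5 <- sim_evolution_trajectories(0.5, k = 0.98, F = 0.5, G = 6, seed = 14)
  t0 <- attr(d0, "truth")$freq
  t5 <- attr(d5, "truth")$freq
  expect_true(all(t0[-1] > t5[-1]))
})

test_that("marker loss reshapes the observed frequency and truncates at 95% loss", {
  # asymmetric loss inflates the focal marker's share among fluorescent cells
  d <- sim_evolution_trajectories(0.5, c = 0, k = 0.5, F = 0, G = 4,
                                  marker_loss = c(0, 0.5), seed = 15)
  truth <- attr(d, "truth")$freq
  expect_true(all(diff(truth) > 0))
  expect_equal(truth[1], 0.5)
  # heavy symmetric loss triggers the stopping rule
  expect_warning(
    d2 <- sim_evolution_trajectories(0.5, c = 0, k = 0.5, F = 0, G = 10,
                                     marker_loss = c(0.6, 0.6), seed = 16),
    "95%")
  expect_lt(max(d2$generation), 10)
})

test_that("census draws recover the generating mating efficiency", {
  cz <- sim_census(0, 1000, seed = 17)
  expect_identical(cz$Z + cz$A + cz$S, 0L)
  expect_gt(cz$V, 0L)
  cf <- sim_census(1, 1000, seed = 18)
  expect_identical(cf$V, 0L)
  expect_equal(mating_efficiency(cf$V, cf$Z, cf$A, cf$S), 100)
  cm <- sim_census(0.4, 100000, seed = 19)
  me_hat <- mating_efficiency(cm$V, cm$Z, cm$A, cm$S)
  expect_lt(abs(me_hat - 40), 1)
})
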