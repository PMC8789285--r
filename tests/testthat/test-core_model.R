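test_that("genotype frequencies reproduce Hardy-Weinberg and inbreeding limits", {
  expect_equal(drop(genotype_freqs(0.5, 0)), c(f11 = 0.25, f12 = 0.5, f22 = 0.25))
  expect_equal(drop(genotype_freqs(0.5, 1)), c(f11 = 0.5, f12 = 0, f22 = 0.5))
  # direct evaluation of the inbreeding-adjusted polynomials
  expect_equal(drop(genotype_freqs(0.3, 0.5)),
               c(f11 = 0.195, f12 = 0.21, f22 = 0.595))
})

test_that("genotype frequencies are a simplex for all feasible (p, F)", {
  p <- seq(0, 1, by = 0.05)
  for (Fv in seq(-0.2, 1, by = 0.1)) {
    f <- suppressWarnings(genotype_freqs(p, Fv))
    expect_true(all(f >= -1e-12))
    expect_equal(rowSums(f), rep(1, nrow(f)), tolerance = 1e-12)
  }
})

test_that("infeasible negative F is clamped with a warning, or errors in strict mode", {
  expect_warning(f <- genotype_freqs(0.1, -1), "clamped")
  expect_equal(rowSums(f), 1, tolerance = 1e-12)
  expect_true(all(f >= 0))
  expect_error(genotype_freqs(0.1, -1, clamp = FALSE), "infeasible")
  # feasible excess heterozygosity does not warn
  expect_silent(genotype_freqs(0.5, -1))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(genotype_freqs(1.2, 0), "\\[0, 1\\]")
  expect_error(genotype_freqs(0.5, 1.5), "\\[-1, 1\\]")
  expect_error(drive_params(k = 0.4), "\\[0.5, 1\\]")
  expect_error(drive_params(k = 1.01), "\\[0.5, 1\\]")
  expect_error(drive_params(w11 = 0, w12 = 0, w22 = 0), "strictly positive")
  expect_error(het_drive_fitness(0.3), "\\[0.5, 1\\]")
  expect_error(fitness_from_costs(1.2, 0), "\\[0, 1\\]")
})

test_that("mean fitness matches the genotype-weighted sum and closed form", {
  expect_equal(mean_fitness(0.5, drive_params(k = 0.98, w12 = 0.51)), 0.755)
  expect_equal(mean_fitness(0.5, drive_params(k = 0.98, w12 = 0.51, F = 1)), 1)
  expect_equal(mean_fitness(0.37, drive_params()), 1)  # neutral normalisation
  # equivalence of the closed form and the frequency-weighted sum
  set.seed(7)
  for (i in 1:50) {
    p <- runif(1); Fv <- runif(1, -min(p, 1 - p) / max(p, 1 - p), 1)
    w <- runif(3, 0.05, 1)
    pars <- drive_params(k = runif(1, 0.5, 1), w11 = w[1], w12 = w[2],
                         w22 = w[3], F = Fv)
    closed <- p^2 * w[1] + 2 * p * (1 - p) * w[2] + (1 - p)^2 * w[3] +
      Fv * p * (1 - p) * (w[1] + w[3] - 2 * w[2])
    expect_equal(mean_fitness(p, pars), closed, tolerance = 1e-12)
  }
})

test_that("the recursion matches hand-computed values and the spore-count oracle", {
  pars <- drive_params(k = 0.98, w12 = 0.51)
  expect_equal(next_freq(0.5, pars), (0.25 + 0.5 * 0.98 * 0.51) / 0.755,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    p <- runif(1); Fv <- runif(1)  # feasible F >= 0
    k <- runif(1, 0.5, 1); w <- runif(3, 0.05, 1)
    pars <- drive_params(k = k, w11 = w[1], w12 = w[2], w22 = w[3], F = Fv)
    expect_equal(next_freq(p, pars),
                 oracle_next_freq(p, k, w[1], w[2], w[3], Fv),
                 tolerance = 1e-12)
  }
})

test_that("0 and 1 are fixed points and [0,1] maps into [0,1]", {
  set.seed(3)
  for (i in 1:20) {
    pars <- drive_params(k = runif(1, 0.5, 1), w11 = runif(1, 0.1, 1),
                         w12 = runif(1, 0.1, 1), w22 = runif(1, 0.1, 1),
                         F = runif(1))
    expect_identical(next_freq(0, pars), 0)
    expect_identical(next_freq(1, pars), 1)
    p <- runif(25)
    pn <- next_freq(p, pars)
    expect_true(all(pn >= 0 & pn <= 1))
  }
})

test_that("exclusive same-clone mating freezes the driver frequency", {
  pars <- drive_params(k = 0.98, w12 = 0.51, F = 1)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(delta_p(p, pars), rep(0, length(p)))
  tr <- drive_trajectory(0.05, pars, 30)
  expect_equal(tr$p, rep(0.05, 31))
})

test_that("Mendelian transmission with equal fitnesses is the identity", {
  for (Fv in c(0, 0.3, 0.9)) {
    pars <- drive_params(k = 0.5, F = Fv)
    p <- seq(0, 1, by = 0.1)
    expect_equal(next_freq(p, pars), p, tolerance = 1e-12)
  }
})

test_that("a pure spore killer spreads from any starting frequency", {
  # w12 = 1/(2k) means heterozygote deaths are the only cost
  for (k in c(0.75, 0.98, 1)) {
    for (Fv in c(0, 0.5, 0.9)) {
      pars <- drive_params(k = k, w12 = het_drive_fitness(k), F = Fv)
      p <- seq(0.01, 0.99, length.out = 99)
      expect_true(all(delta_p(p, pars) > 0))
    }
  }
})

test_that("trajectories iterate the recursion and approach fixation under drive", {
  expect_equal(drive_trajectory(0.05, drive_params(), 0)$p, 0.05)
  pars <- drive_params(k = 0.98, w12 = 0.51)
  tr <- drive_trajectory(0.05, pars, 30)
  expect_equal(nrow(tr), 31L)
  expect_equal(tr$generation, 0:30)
  expect_true(all(diff(tr$p) > 0))
  expect_gt(tr$p[31], 0.99)
  expect_equal(tr$p[2], next_freq(0.05, pars))
})

test_that("drive-implied heterozygote fitness follows 1/(2k)", {
  expect_equal(het_drive_fitness(0.98), 1 / 1.96)
  expect_equal(round(het_drive_fitness(0.98), 2), 0.51)
  expect_equal(het_drive_fitness(0.5), 1)
  expect_equal(het_drive_fitness(1), 0.5)
})

test_that("cost-based fitness assignment reproduces the documented values", {
  w <- fitness_from_costs(0.234, 0.083)
  expect_equal(unname(w["w11"]), 0.766)
  expect_equal(round(unname(w["w12"]), 2), 0.98)
  expect_equal(unname(w["w22"]), 1)
  # cost on the other allele swaps the homozygotes
  w2 <- fitness_from_costs(0.234, 0.083, driver_linked_to_costly = FALSE)
  expect_equal(unname(w2["w22"]), 0.766)
  expect_equal(unname(w2["w11"]), 1)
  # zero cost leaves only the drive adjustment
  w3 <- fitness_from_costs(0, 0.5, k = 0.98)
  expect_equal(unname(w3), c(1, het_drive_fitness(0.98), 1))
  # drive and cost combine multiplicatively in the heterozygote
  w4 <- fitness_from_costs(0.234, 0.083, k = 0.98)
  expect_equal(unname(w4["w12"]), (1 - 0.234 * 0.083) / 1.96)
})
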