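#' Configuration for finite-population drive simulations
#'
#' Parameters of the stochastic Wright-Fisher model of a wtf-type driver in
#' a haploid population of size `N` with a same-clone-mating fraction `F`.
#' Each generation, `N` individuals are resampled with replacement from the
#' current pool (an infinite-gamete assumption, as if the population expanded
#' mitotically before mating); a fraction `F` of them mate with a clonal copy
#' of themselves, the rest mate at random in Hardy-Weinberg proportions.
#' Homozygous matings yield four spores of the parental allele; under
#' complete drive a heterozygous mating's surviving spores all carry the
#' driver, the drive-induced deaths being captured by `het_fitness`
#' (default 0.5: half of four spores). Each mating class's spore output is
#' thinned in proportion to its fitness, and the next generation of `N`
#' haploids is drawn uniformly from the pooled survivors.
#'
#' @param N Haploid population size (positive integer).
#' @param F Same-clone-mating (inbreeding) fraction, in `[0, 1]`.
#' @param generations Generation cap (default 1000).
#' @param iterations Monte-Carlo replicates for [maintenance_probability()]
#'   (default 1000).
#' @param initial_driver_count Starting number of driver haploids (default 1).
#' @param het_fitness Fitness of heterozygous matings in `[0, 1]`. The
#'   default 0.5 encodes complete drive with no extra linked cost.
#' @param hom_driver_fitness,hom_nondriver_fitness Fitness of the two
#'   homozygous mating classes, in `[0, 1]` (default 1).
#' @param drive_mode `"complete"`: surviving spores of heterozygotes all
#'   carry the driver. `"neutral"`: Mendelian transmission; surviving spores
#'   of heterozygotes carry either allele with equal probability (set
#'   `het_fitness = 1` for a fully neutral model).
#' @param pairing `"clone"` (default): each inbreeding individual mates with
#'   a clonal copy of itself. `"like"`: inbreeding individuals are paired
#'   like-for-like among themselves; odd leftovers join the random maters.
#' @param decimation `"stochastic"` (default): binomial thinning of each
#'   mating class's spores by its fitness; `"deterministic"`: rounded
#'   proportional truncation.
#' @param hw_rounding How Hardy-Weinberg genotype proportions of the random
#'   maters are turned into integer counts. `"stochastic"` (default) floors
#'   the quotas and assigns the leftover matings multinomially in proportion
#'   to the fractional parts, which keeps the expected allele count exact
#'   (a neutral model stays a martingale). `"largest-remainder"` is the
#'   deterministic alternative; it introduces a small per-state allele
#'   drift in small populations.
#' @param record_trajectory Record per-generation driver counts in
#'   [wf_run()] output (default `TRUE`).
#' @param trajectory_thin Keep every `trajectory_thin`-th generation of the
#'   recorded trajectory (default 1 = all).
#' @param seed Master RNG seed (integer or `NULL`).
#' @return An object of class `wf_config`.
#' @examples
#' wf_config(N = 100, F = 0.5, seed = 1)
#' @export
wf_config <- function(N, F = 0, generations = 1000L, iterations = 1000L,
                      initial_driver_count = 1L,
                      het_fitness = 0.5, hom_driver_fitness = 1,
                      hom_nondriver_fitness = 1,
                      drive_mode = c("complete", "neutral"),
                      pairing = c("clone", "like"),
                      decimation = c("stochastic", "deterministic"),
                      hw_rounding = c("stochastic", "largest-remainder"),
                      record_trajectory = TRUE, trajectory_thin = 1L,
                      seed = NULL) {
  drive_mode <- match.arg(drive_mode)
  pairing <- match.arg(pairing)
  decimation <- match.arg(decimation)
  hw_rounding <- match.arg(hw_rounding)
  stopifnot(length(N) == 1L, N >= 1, N == as.integer(N),
            length(F) == 1L, F >= 0, F <= 1,
            generations >= 0, iterations >= 1,
            initial_driver_count >= 0, initial_driver_count <= N,
            het_fitness >= 0, het_fitness <= 1,
            hom_driver_fitness >= 0, hom_driver_fitness <= 1,
            hom_nondriver_fitness >= 0, hom_nondriver_fitness <= 1,
            trajectory_thin >= 1)
  structure(list(N = as.integer(N), F = F,
                 generations = as.integer(generations),
                 iterations = as.integer(iterations),
                 initial_driver_count = as.integer(initial_driver_count),
                 het_fitness = het_fitness,
                 hom_driver_fitness = hom_driver_fitness,
                 hom_nondriver_fitness = hom_nondriver_fitness,
                 drive_mode = drive_mode, pairing = pairing,
                 decimation = decimation, hw_rounding = hw_rounding,
                 record_trajectory = isTRUE(record_trajectory),
                 trajectory_thin = as.integer(trajectory_thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "wf_config")
}

#' @export
print.wf_config <- function(x, ...) {
  cat(sprintf("Wright-Fisher drive simulation: N = %d, F = %.3g, %s drive\n",
              x$N, x$F, x$drive_mode))
  cat(sprintf("  start %d/%d drivers; fitness het %.3g, hom %.3g/%.3g; cap %d generations\n",
              x$initial_driver_count, x$N, x$het_fitness,
              x$hom_driver_fitness, x$hom_nondriver_fitness, x$generations))
  invisible(x)
}

# Split decimated spore output for one mating class.
thin_class <- function(n_spores, fitness, decimation) {
  if (n_spores == 0 || fitness == 0) return(0L)
  if (fitness == 1) return(as.integer(n_spores))
  if (decimation == "stochastic") {
    stats::rbinom(1L, n_spores, fitness)
  } else {
    as.integer(round(n_spores * fitness))
  }
}

#' Advance a finite drive population by one generation
#'
#' One Wright-Fisher generation as described in [wf_config()]: resample `N`
#' individuals with replacement, form same-clone and random matings, produce
#' four spores per mating (heterozygote survivors all carry the driver under
#' complete drive), thin each mating class by its fitness, and draw the next
#' `N` haploids uniformly from the surviving spore pool. Counts 0 and `N`
#' are absorbing. Uses the current RNG stream; seed control belongs to
#' [wf_run()] and [maintenance_probability()].
#'
#' @param driver_count Current number of driver haploids, in `[0, N]`.
#' @param config A [wf_config()] object.
#' @return The next generation's driver count, or `NA_integer_` if the
#'   entire spore pool was eliminated by selection (population extinction).
#' @export
wf_step <- function(driver_count, config) {
  stopifnot(inherits(config, "wf_config"),
            length(driver_count) == 1L, !is.na(driver_count),
            driver_count >= 0, driver_count <= config$N)
  n <- config$N
  d0 <- as.integer(driver_count)
  if (d0 == 0L || d0 == n) return(d0)

  # (1) resample n individuals with replacement from the haploid pool
  d <- stats::rbinom(1L, n, d0 / n)

  # (2) designate same-clone maters (sampled without replacement)
  S <- as.integer(round(config$F * n))
  d_in <- stats::rhyper(1L, d, n - d, S)

  if (config$pairing == "clone") {
    n11 <- d_in
    n22 <- S - d_in
    m <- n - S
    d_rand <- d - d_in
  } else { # like-for-like pairs; odd leftovers mate randomly
    n11 <- d_in %/% 2L
    n22 <- (S - d_in) %/% 2L
    m <- n - 2L * (n11 + n22)
    d_rand <- d - 2L * n11
  }

  # (3) random maters in Hardy-Weinberg proportions, integerised
  if (m > 0L) {
    q <- d_rand / m
    apportion <- if (config$hw_rounding == "stochastic") stochastic_remainder
                 else largest_remainder
    hw <- apportion(m, c(q^2, 2 * q * (1 - q), (1 - q)^2))
    n11 <- n11 + hw[1L]; n12 <- hw[2L]; n22 <- n22 + hw[3L]
  } else {
    n12 <- 0L
  }

  # (4)+(5) four spores per mating, thinned by mating-class fitness
  drv <- thin_class(4L * n11, config$hom_driver_fitness, config$decimation)
  non <- thin_class(4L * n22, config$hom_nondriver_fitness, config$decimation)
  het <- thin_class(4L * n12, config$het_fitness, config$decimation)
  if (config$drive_mode == "complete") {
    drv <- drv + het
  } else {
    het_d <- stats::rbinom(1L, het, 0.5)
    drv <- drv + het_d
    non <- non + (het - het_d)
  }

  # (6) next generation drawn uniformly from the pooled spores
  pool <- drv + non
  if (pool == 0L) return(NA_integer_)
  if (pool >= n) {
    stats::rhyper(1L, drv, non, n)
  } else {
    stats::rbinom(1L, n, drv / pool)
  }
}

#' Run one finite-population drive simulation to absorption or the cap
#'
#' Iterates [wf_step()] from `config$initial_driver_count` until the driver
#' fixes, is lost, the population goes extinct, or `config$generations` is
#' reached.
#'
#' @param config A [wf_config()] object; `config$seed`, when non-`NULL`,
#'   makes the run reproducible without disturbing the caller's RNG state.
#' @return An object of class `wf_outcome`: a list with `fate` (one of
#'   `"fixed"`, `"lost"`, `"segregating"`, `"extinct"`),
#'   `generations_elapsed`, `final_count`, and (optionally) `trajectory`, a
#'   data frame of per-generation driver counts thinned by
#'   `config$trajectory_thin`.
#' @examples
#' wf_run(wf_config(N = 50, F = 0, initial_driver_count = 5, seed = 42))
#' @export
wf_run <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  with_seed(config$seed, {
    n <- config$N
    count <- config$initial_driver_count
    counts <- if (config$record_trajectory) integer(config$generations + 1L)
    if (config$record_trajectory) counts[1L] <- count
    g <- 0L
    extinct <- FALSE
    while (g < config$generations && count > 0L && count < n) {
      g <- g + 1L
      count <- wf_step(count, config)
      if (is.na(count)) {
        extinct <- TRUE
        count <- 0L
      }
      if (config$record_trajectory) counts[g + 1L] <- count
      if (extinct) break
    }
    fate <- if (extinct) "extinct"
            else if (count == 0L) "lost"
            else if (count == n) "fixed"
            else "segregating"
    traj <- NULL
    if (config$record_trajectory) {
      gen <- 0:g
      keep <- gen %% config$trajectory_thin == 0L | gen == g
      traj <- data.frame(generation = gen[keep],
                         driver_count = counts[seq_len(g + 1L)][keep])
    }
    structure(list(fate = fate, generations_elapsed = g,
                   final_count = count, trajectory = traj,
                   config = config),
              class = "wf_outcome")
  })
}

#' @export
print.wf_outcome <- function(x, ...) {
  cat(sprintf("Wright-Fisher run: %s after %d generations (final count %d/%d)\n",
              x$fate, x$generations_elapsed, x$final_count, x$config$N))
  invisible(x)
}

#' Probability that a driver is maintained in a finite population
#'
#' Runs `config$iterations` independent replicates of [wf_run()] and reports
#' the fraction in which the driver is not lost by the generation cap
#' (i.e. fixed or still segregating), with its binomial Monte-Carlo standard
#' error. Fixed-only and segregating tallies are reported separately as
#' well, since "maintained" can be read either way. Replicates use sub-seeds
#' derived from `config$seed`, so runs with the same master seed share
#' replicate streams across configurations (common random numbers).
#'
#' @param config A [wf_config()] object.
#' @return A list of class `wf_maintenance` with elements `estimate`, `se`,
#'   `n_maintained`, `n_fixed`, `n_lost`, `n_segregating`, `n_extinct`,
#'   `iterations`, and `config`.
#' @examples
#' maintenance_probability(wf_config(N = 20, iterations = 100, seed = 7))
#' @export
maintenance_probability <- function(config) {
  stopifnot(inherits(config, "wf_config"), config$iterations >= 1L)
  fates <- character(config$iterations)
  for (i in seq_len(config$iterations)) {
    cfg_i <- config
    cfg_i$record_trajectory <- FALSE
    cfg_i$seed <- if (is.null(config$seed)) NULL else derive_seed(config$seed, i)
    fates[i] <- wf_run(cfg_i)$fate
  }
  n_lost <- sum(fates == "lost") + sum(fates == "extinct")
  n_maint <- config$iterations - n_lost
  est <- n_maint / config$iterations
  structure(list(estimate = est,
                 se = sqrt(est * (1 - est) / config$iterations),
                 n_maintained = n_maint,
                 n_fixed = sum(fates == "fixed"),
                 n_lost = sum(fates == "lost"),
                 n_segregating = sum(fates == "segregating"),
                 n_extinct = sum(fates == "extinct"),
                 iterations = config$iterations,
                 config = config),
            class = "wf_maintenance")
}

#' @export
print.wf_maintenance <- function(x, ...) {
  cat(sprintf("Driver maintenance probability: %.4f +/- %.4f (N = %d, F = %.3g, %d replicates)\n",
              x$estimate, x$se, x$config$N, x$config$F, x$iterations))
  cat(sprintf("  fixed %d, segregating %d, lost %d, extinct %d\n",
              x$n_fixed, x$n_segregating, x$n_lost, x$n_extinct))
  invisible(x)
}
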