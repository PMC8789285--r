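#' Simulate zygote genotype counts from a mating round
#'
#' Multinomial draw of `n_zygotes` mated cells from the genotype
#' frequencies implied by allele frequency `p` and inbreeding coefficient
#' `F` ([genotype_freqs()]). The result is the synthetic analogue of a
#' microscopy fluorescence-classified zygote/ascus table and feeds directly
#' into [inbreeding_from_zygotes()].
#'
#' @param p True frequency of parent 1 before mating, in `[0, 1]`.
#' @param F True inbreeding coefficient, in `[-1, 1]`.
#' @param n_zygotes Number of mated cells to draw (>= 0).
#' @param seed RNG seed (optional); the caller's RNG state is preserved.
#' @return A [zygote_counts()] object with `p_initial = p` and the seed
#'   stored in attribute `"seed"`.
#' @examples
#' sim_zygote_counts(0.5, F = 0.5, n_zygotes = 1000, seed = 1)
#' @export
sim_zygote_counts <- function(p, F, n_zygotes, seed = NULL) {
  stopifnot(length(n_zygotes) == 1L, n_zygotes >= 0)
  f <- drop(genotype_freqs(p, F))
  with_seed(seed, {
    x <- if (n_zygotes == 0) c(0L, 0L, 0L) else
      drop(stats::rmultinom(1L, n_zygotes, f))
    out <- zygote_counts(x[1L], x[2L], x[3L], p_initial = p)
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a progeny marker-genotype table
#'
#' Generates the progeny of a cross scored at `n_markers` unlinked loci.
#' Each progeny first draws its parental mating type from
#' [genotype_freqs()]`(p, F)`: homozygous matings emit the corresponding
#' parental multilocus genotype; heterozygous (outcross) matings emit one of
#' the `2^n_markers` marker combinations uniformly (unlinked Mendelian
#' segregation). This is the input of the genetic inbreeding estimator
#' ([recombinant_fraction()], [inbreeding_from_genetic()]).
#'
#' @param p Frequency of parent 1 before mating, in `[0, 1]`.
#' @param F Inbreeding coefficient, in `[-1, 1]`.
#' @param n_markers Number of unlinked markers, 2 or 3.
#' @param n_progeny Number of progeny to draw (>= 1).
#' @param seed RNG seed (optional).
#' @return A data frame with one row per progeny and columns `m1`, `m2`,
#'   ... coded 1/2 for parental origin; attribute `parental_genotypes`
#'   holds the two parental multilocus genotypes, attribute `"seed"` the
#'   seed.
#' @examples
#' sim_progeny_table(0.5, F = 0, n_markers = 3, n_progeny = 10, seed = 1)
#' @export
sim_progeny_table <- function(p, F, n_markers, n_progeny, seed = NULL) {
  if (!n_markers %in% c(2L, 3L)) stop("'n_markers' must be 2 or 3")
  stopifnot(length(n_progeny) == 1L, n_progeny >= 1)
  f <- drop(genotype_freqs(p, F))
  with_seed(seed, {
    # categories follow genotype_freqs columns: 1 = hom1, 2 = het, 3 = hom2
    mating <- sample.int(3L, n_progeny, replace = TRUE, prob = f)
    geno <- matrix(0L, nrow = n_progeny, ncol = n_markers,
                   dimnames = list(NULL, paste0("m", seq_len(n_markers))))
    het <- mating == 2L
    geno[mating == 1L, ] <- 1L
    geno[mating == 3L, ] <- 2L
    if (any(het)) {
      geno[het, ] <- matrix(sample(c(1L, 2L), sum(het) * n_markers,
                                   replace = TRUE),
                            ncol = n_markers)
    }
    out <- as.data.frame(geno)
    attr(out, "parental_genotypes") <- list(rep(1L, n_markers),
                                            rep(2L, n_markers))
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate fluorophore-frequency trajectories from experimental evolution
#'
#' Forward-simulates the deterministic drive recursion ([drive_trajectory()])
#' with fitnesses built by [fitness_from_costs()], then layers on the two
#' observational features of cytometry-based experimental evolution:
#' optional per-generation fluorescent-marker loss, and binomial measurement
#' noise with `effective_n` scored cells per observation. The reported
#' frequency is that of the focal (driver) allele's marker *among
#' fluorescent cells*.
#'
#' Marker loss is a per-lineage, per-generation excision probability,
#' independent of genotype; `marker_loss[1]` applies to the focal allele's
#' fluorophore, `marker_loss[2]` to the other (mCherry-type markers are
#' typically lost faster, but rates default to 0 so loss is opt-in). When
#' more than 95% of cells have lost fluorescence the trajectory is
#' truncated with a warning, mirroring the practical stopping rule of such
#' experiments.
#'
#' @param p0 Initial driver-allele frequency, in `[0, 1]`.
#' @param c,h Linked cost and dominance (passed to [fitness_from_costs()]).
#' @param k Transmission bias of the driver; 0.5 = no drive (controls).
#' @param F Inbreeding coefficient.
#' @param costly_allele Which allele carries the cost: `"focal"` (the
#'   driver, default), `"other"`, or `"none"` (force `c = 0`).
#' @param G Number of sexual generations.
#' @param replicates Number of replicate trajectories (independent noise).
#' @param effective_n Cells scored per observation (binomial denominator).
#' @param marker_loss Length-2 per-generation loss probabilities, default
#'   `c(0, 0)`.
#' @param seed RNG seed (optional).
#' @return A data frame of class `observed_trajectories` with columns
#'   `replicate`, `generation` (0 .. G or the truncation point), `freq`,
#'   `effective_n`; attributes `truth` (the noise-free observed-frequency
#'   curve) and `"seed"`.
#' @examples
#' sim_evolution_trajectories(0.5, c = 0.234, h = 0.083, k = 0.5, F = 0.5,
#'                            G = 6, replicates = 3, seed = 1)
#' @export
sim_evolution_trajectories <- function(p0, c = 0, h = 0, k = 0.5, F = 0,
                                       costly_allele = c("focal", "other", "none"),
                                       G = 6L, replicates = 3L,
                                       effective_n = 10000L,
                                       marker_loss = c(0, 0), seed = NULL) {
  costly_allele <- match.arg(costly_allele)
  stopifnot(length(marker_loss) == 2L, all(marker_loss >= 0),
            all(marker_loss < 1), G >= 0, replicates >= 1, effective_n >= 1)
  w <- if (costly_allele == "none") {
    fitness_from_costs(0, 0, k = k)
  } else {
    fitness_from_costs(c, h, k = k,
                       driver_linked_to_costly = costly_allele == "focal")
  }
  pars <- drive_params(k = k, w11 = w[["w11"]], w12 = w[["w12"]],
                       w22 = w[["w22"]], F = F)
  traj <- drive_trajectory(p0, pars, G)
  gen <- traj$generation
  p <- traj$p
  s1 <- (1 - marker_loss[1L])^gen
  s2 <- (1 - marker_loss[2L])^gen
  fluor <- p * s1 + (1 - p) * s2
  if (any(fluor < 0.05)) {
    cut <- which(fluor < 0.05)[1L] - 1L
    warning("more than 95% of cells lost fluorescence at generation ",
            gen[cut + 1L], "; trajectory truncated at generation ", gen[cut])
    keep <- seq_len(cut)
    gen <- gen[keep]; p <- p[keep]; s1 <- s1[keep]; s2 <- s2[keep]
    fluor <- fluor[keep]
  }
  mu <- ifelse(fluor > 0, p * s1 / fluor, NA_real_)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      obs <- stats::rbinom(length(mu), effective_n, mu) / effective_n
      data.frame(replicate = r, generation = gen, freq = obs,
                 effective_n = as.integer(effective_n))
    }))
    rownames(out) <- NULL
    class(out) <- c("observed_trajectories", "data.frame")
    attr(out, "truth") <- data.frame(generation = gen, freq = mu)
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a vegetative/zygote/ascus/spore census
#'
#' Calibration input for [mating_efficiency()]: draws the number of mated
#' cells as `Binomial(n_cells, me_true)` and distributes them among zygotes,
#' asci and free spores according to `ascus_mix` (two cells per zygote or
#' ascus, two free spores per mated cell). Vegetative cells are reported on
#' the same weighted scale as the default mating-efficiency formula (weight
#' 2 per unmated cell), so that the estimator recovers `me_true` in
#' expectation under its default weights.
#'
#' @param me_true True mating efficiency as a fraction in `[0, 1]`.
#' @param n_cells Total cells observed (>= 1).
#' @param ascus_mix Length-3 non-negative weights (summing to 1) giving the
#'   fractions of mated cells scored as zygotes, asci, and free spores.
#' @param seed RNG seed (optional).
#' @return A list of class `cell_census` with integer fields `V`, `Z`, `A`,
#'   `S` and attribute `"seed"`.
#' @examples
#' sim_census(0.4, n_cells = 1e5, seed = 1)
#' @export
sim_census <- function(me_true, n_cells, ascus_mix = c(0.5, 0.3, 0.2),
                       seed = NULL) {
  stopifnot(length(me_true) == 1L, me_true >= 0, me_true <= 1,
            n_cells >= 1, length(ascus_mix) == 3L, all(ascus_mix >= 0))
  if (abs(sum(ascus_mix) - 1) > 1e-9) stop("'ascus_mix' must sum to 1")
  with_seed(seed, {
    mated <- stats::rbinom(1L, n_cells, me_true)
    split <- largest_remainder(mated, ascus_mix)
    out <- structure(list(V = as.integer(round((n_cells - mated) / 2)),
                          Z = as.integer(round(split[1L] / 2)),
                          A = as.integer(round(split[2L] / 2)),
                          S = as.integer(2L * split[3L])),
                     class = "cell_census")
    attr(out, "seed") <- seed
    out
  })
}

#' @export
print.cell_census <- function(x, ...) {
  cat(sprintf("Cell census: V %d, Z %d, A %d, S %d\n", x$V, x$Z, x$A, x$S))
  invisible(x)
}
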