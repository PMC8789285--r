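#' Parameters of the one-locus meiotic drive model
#'
#' Bundles the parameters of the deterministic drive model: the transmission
#' bias `k` of the driver allele from heterozygotes, the relative fitnesses of
#' the three diploid genotypes, and the inbreeding coefficient `F` of the
#' population.
#'
#' Allele 1 is the driver (or focal) allele throughout the package: `w11` is
#' the fitness of driver homozygotes, `w22` of non-driver homozygotes.
#' `k = 0.5` is Mendelian transmission (no drive); `k = 1` is complete drive.
#' `F` follows the usual heterozygote-deficit convention: `F = 1` means
#' exclusive like-with-like (e.g. same-clone) mating, `F = 0` random mating,
#' negative values an excess of heterozygotes.
#'
#' @param k Transmission probability of the driver allele from a heterozygote,
#'   in `[0.5, 1]`. Values below 0.5 (drive against the focal allele) are
#'   rejected.
#' @param w11,w12,w22 Relative fitnesses of driver homozygotes, heterozygotes
#'   and non-driver homozygotes, each in `[0, 1]`; at least one must be
#'   strictly positive.
#' @param F Inbreeding coefficient, in `[-1, 1]`.
#'
#' @return An object of class `drive_params` (a named list with the five
#'   components).
#'
#' @examples
#' # complete drive, spore killing only (heterozygote fitness 1/(2k)), random mating
#' drive_params(k = 1, w12 = het_drive_fitness(1))
#'
#' @seealso [het_drive_fitness()], [fitness_from_costs()], [next_freq()]
#' @export
drive_params <- function(k = 0.5, w11 = 1, w12 = 1, w22 = 1, F = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k < 0.5 || k > 1) {
    stop("'k' must lie in [0.5, 1] (0.5 = Mendelian, 1 = complete drive)")
  }
  for (nm in c("w11", "w12", "w22")) {
    w <- get(nm)
    stopifnot(is.numeric(w), length(w) == 1L, is.finite(w))
    if (w < 0 || w > 1) stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (w11 == 0 && w12 == 0 && w22 == 0) {
    stop("at least one genotype fitness must be strictly positive")
  }
  stopifnot(is.numeric(F), length(F) == 1L, is.finite(F))
  if (F < -1 || F > 1) stop("'F' must lie in [-1, 1]")
  structure(list(k = k, w11 = w11, w12 = w12, w22 = w22, F = F),
            class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat("Meiotic drive model parameters\n")
  cat(sprintf("  transmission bias k : %.4g%s\n", x$k,
              if (x$k == 0.5) " (Mendelian)" else if (x$k == 1) " (complete drive)" else ""))
  cat(sprintf("  fitness w11/w12/w22 : %.4g / %.4g / %.4g\n", x$w11, x$w12, x$w22))
  cat(sprintf("  inbreeding F        : %.4g\n", x$F))
  invisible(x)
}

#' Heterozygote fitness implied by drive-induced spore killing
#'
#' A wtf-type driver kills the spores of a heterozygote that do not inherit
#' it. If a fraction `k` of the surviving spores carry the driver and there is
#' no other cost, the heterozygote's relative fitness is `1 / (2 k)`: at
#' `k = 1` half of the four spores die (fitness 0.5), at `k = 0.5` none do.
#'
#' @param k Transmission bias in `[0.5, 1]`.
#' @return Heterozygote relative fitness in `[0.5, 1]`.
#' @examples
#' het_drive_fitness(0.98) # ~0.51
#' @export
het_drive_fitness <- function(k) {
  stopifnot(is.numeric(k), all(is.finite(k)))
  if (any(k < 0.5 | k > 1)) stop("'k' must lie in [0.5, 1]")
  1 / (2 * k)
}

#' Genotype fitnesses from a linked cost, its dominance, and drive strength
#'
#' Builds the `(w11, w12, w22)` fitness triple for a driver allele that may be
#' linked to a deleterious marker (e.g. a fluorophore insertion) with
#' homozygous cost `c` and dominance `h`. Homozygotes for the costly marker
#' have fitness `1 - c`, heterozygotes carry the factor `1 - c h`, and the
#' cost-free homozygote has fitness 1. Heterozygotes are additionally
#' penalised by drive-induced spore killing, multiplying their fitness by
#' `1/(2 k)` ([het_drive_fitness()]); with `k = 0.5` this factor is 1.
#'
#' @param c Homozygous fitness cost of the linked marker, in `[0, 1]`.
#' @param h Dominance of the cost, in `[0, 1]` (heterozygous cost `c * h`).
#' @param k Transmission bias of the driver, in `[0.5, 1]`; default `0.5`
#'   (no drive, e.g. empty-vector controls).
#' @param driver_linked_to_costly If `TRUE` (default) the driver allele
#'   (allele 1) carries the costly marker, so `w11 = 1 - c`; if `FALSE` the
#'   cost sits on the non-driver allele, so `w22 = 1 - c`.
#'
#' @return Named numeric vector `c(w11, w12, w22)`.
#' @examples
#' fitness_from_costs(c = 0.234, h = 0.083)            # GFP-like cost, no drive
#' fitness_from_costs(c = 0.234, h = 0.083, k = 0.98)  # cost plus drive
#' @export
fitness_from_costs <- function(c, h, k = 0.5, driver_linked_to_costly = TRUE) {
  stopifnot(length(c) == 1L, length(h) == 1L, length(k) == 1L,
            is.finite(c), is.finite(h), is.finite(k))
  if (c < 0 || c > 1) stop("'c' must lie in [0, 1]")
  if (h < 0 || h > 1) stop("'h' must lie in [0, 1]")
  if (k < 0.5 || k > 1) stop("'k' must lie in [0.5, 1]")
  w12 <- unname((1 - c * h) * het_drive_fitness(k))
  if (driver_linked_to_costly) {
    c(w11 = unname(1 - c), w12 = w12, w22 = 1)
  } else {
    c(w11 = 1, w12 = w12, w22 = unname(1 - c))
  }
}
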