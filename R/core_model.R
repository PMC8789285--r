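#' Diploid genotype frequencies under partial inbreeding
#'
#' Genotype frequencies among newly formed zygotes when an allele at
#' frequency `p` mates in a population with inbreeding coefficient `F`:
#' \deqn{f_{11} = p^2 + F p (1-p),\quad
#'       f_{12} = 2 p (1-p) (1-F),\quad
#'       f_{22} = (1-p)^2 + F p (1-p).}
#' `F = 0` recovers Hardy-Weinberg proportions and `F = 1` eliminates
#' heterozygotes.
#'
#' For `F < 0` (heterozygote excess) the raw homozygote terms can go negative
#' when `|F|` exceeds what the allele frequency permits. By default such
#' frequencies are clamped to zero and the triple renormalised to sum to 1,
#' with a warning; with `clamp = FALSE` an error is raised instead. The clamp
#' makes strongly negative `F` usable across the whole frequency range, at
#' the price of no longer being the literal polynomial.
#'
#' @param p Allele-1 frequency, numeric vector in `[0, 1]`.
#' @param F Inbreeding coefficient in `[-1, 1]`.
#' @param clamp Clamp-and-renormalise infeasible negative frequencies
#'   (default) or raise an error.
#' @return Numeric matrix with one row per element of `p` and columns
#'   `f11`, `f12`, `f22`; rows sum to 1.
#' @examples
#' genotype_freqs(0.5, F = 0)   # 0.25 0.50 0.25
#' genotype_freqs(0.5, F = 1)   # 0.50 0.00 0.50
#' @export
genotype_freqs <- function(p, F, clamp = TRUE) {
  stopifnot(is.numeric(p), all(is.finite(p)),
            is.numeric(F), length(F) == 1L, is.finite(F))
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  if (F < -1 || F > 1) stop("'F' must lie in [-1, 1]")
  pq <- p * (1 - p)
  f <- cbind(f11 = p^2 + F * pq,
             f12 = 2 * pq * (1 - F),
             f22 = (1 - p)^2 + F * pq)
  neg <- f < 0
  if (any(neg)) {
    if (!clamp) {
      stop("negative genotype frequency: F = ", F,
           " is infeasible at this allele frequency (set clamp = TRUE to renormalise)")
    }
    warning("negative genotype frequencies at F = ", F,
            " clamped to 0 and renormalised")
    f[neg] <- 0
    f <- f / rowSums(f)
  }
  f
}

#' Population mean fitness at a given allele frequency
#'
#' The mean relative fitness of zygotes,
#' \eqn{\bar W = f_{11} w_{11} + f_{12} w_{12} + f_{22} w_{22}}, which for
#' feasible `(p, F)` equals the closed form
#' \eqn{p^2 w_{11} + 2p(1-p) w_{12} + (1-p)^2 w_{22}
#'      + F p (1-p)(w_{11} + w_{22} - 2 w_{12})}.
#'
#' @param p Allele-1 frequency, numeric vector in `[0, 1]`.
#' @param params A [drive_params()] object.
#' @inheritParams genotype_freqs
#' @return Numeric vector of mean fitnesses; an error is raised if any value
#'   is not strictly positive (selection would destroy the whole population).
#' @export
mean_fitness <- function(p, params, clamp = TRUE) {
  stopifnot(inherits(params, "drive_params"))
  f <- genotype_freqs(p, params$F, clamp = clamp)
  w <- drop(f %*% c(params$w11, params$w12, params$w22))
  if (any(w <= 0)) {
    stop("mean fitness is not positive: all contributing genotypes have zero fitness")
  }
  w
}

#' One round of sexual reproduction: the allele-frequency recursion
#'
#' Driver allele frequency after one generation of mating, meiosis with
#' transmission bias `k`, and selection:
#' \deqn{p' = \frac{[p^2 + F p(1-p)]\, w_{11} + 2p(1-p)\,k\,(1-F)\, w_{12}}
#'                 {\bar W}.}
#' Homozygous matings transmit their own allele; heterozygotes transmit the
#' driver to a fraction `k` of their surviving spores. Frequencies 0 and 1
#' are fixed points for every parameter combination.
#'
#' @inheritParams mean_fitness
#' @return Numeric vector of next-generation allele frequencies in `[0, 1]`.
#' @examples
#' pars <- drive_params(k = 0.98, w12 = het_drive_fitness(0.98))
#' next_freq(0.5, pars)
#' @export
next_freq <- function(p, params, clamp = TRUE) {
  stopifnot(inherits(params, "drive_params"))
  f <- genotype_freqs(p, params$F, clamp = clamp)
  wbar <- drop(f %*% c(params$w11, params$w12, params$w22))
  if (any(wbar <= 0)) {
    stop("mean fitness is not positive: the recursion is undefined")
  }
  pn <- (f[, "f11"] * params$w11 + f[, "f12"] * params$k * params$w12) / wbar
  unname(pmin(pmax(pn, 0), 1))
}

#' Per-generation change in driver frequency
#'
#' `delta_p(p, params)` is `next_freq(p, params) - p`: positive where the
#' driver gains ground in one sexual generation, zero at the absorbing
#' boundaries and at equilibria.
#'
#' @inheritParams next_freq
#' @return Numeric vector of frequency changes in `[-1, 1]`.
#' @export
delta_p <- function(p, params, clamp = TRUE) {
  next_freq(p, params, clamp = clamp) - p
}

#' Iterate the drive recursion over consecutive sexual generations
#'
#' Applies [next_freq()] `generations` times starting from `p0`, returning
#' the full deterministic trajectory.
#'
#' @param p0 Initial driver allele frequency in `[0, 1]`.
#' @param params A [drive_params()] object.
#' @param generations Number of sexual generations to simulate (>= 0).
#' @inheritParams genotype_freqs
#' @return A `drive_trajectory`: a data frame with columns `generation`
#'   (0 to `generations`) and `p`.
#' @examples
#' pars <- drive_params(k = 0.98, w12 = het_drive_fitness(0.98))
#' drive_trajectory(0.05, pars, 30)
#' @export
drive_trajectory <- function(p0, params, generations, clamp = TRUE) {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0),
            p0 >= 0, p0 <= 1,
            length(generations) == 1L, generations >= 0,
            generations == as.integer(generations))
  generations <- as.integer(generations)
  p <- numeric(generations + 1L)
  p[1L] <- p0
  if (generations > 0L) {
    for (g in seq_len(generations)) {
      p[g + 1L] <- next_freq(p[g], params, clamp = clamp)
    }
  }
  structure(data.frame(generation = 0:generations, p = p),
            class = c("drive_trajectory", "data.frame"),
            params = params)
}

#' @export
print.drive_trajectory <- function(x, ...) {
  cat(sprintf("Deterministic drive trajectory: %d generations, p0 = %.4g, final p = %.4g\n",
              nrow(x) - 1L, x$p[1L], x$p[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
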