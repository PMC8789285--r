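#' Critical inbreeding coefficient for a driver linked to a deleterious allele
#'
#' Under complete drive (`k = 1`), a driver carrying a linked cost `c` with
#' dominance `h` (genotype fitnesses `w11 = 1 - c`, `w12 = (1 - c h)/2`,
#' `w22 = 1`) increases in frequency from `p` exactly when the population's
#' inbreeding coefficient is below
#' \deqn{F_{crit} = \frac{c h (p-1) - c p + p}{c (h-1)(p-1) + p}.}
#' With no linked cost (`c = 0`) the threshold is 1: the driver spreads under
#' any amount of inbreeding short of exclusive same-clone mating.
#'
#' @param p Initial driver frequency, in `(0, 1)` (vectorised).
#' @param c Linked homozygous fitness cost in `[0, 1]`.
#' @param h Dominance of the cost in `[0, 1]`.
#' @return Numeric vector of critical inbreeding coefficients; the driver
#'   spreads iff `F < critical_inbreeding(p, c, h)`.
#' @examples
#' critical_inbreeding(0.25, c = 0.234, h = 0.083)
#' @export
critical_inbreeding <- function(p, c, h) {
  stopifnot(is.numeric(p), is.numeric(c), is.numeric(h),
            all(is.finite(p)), all(is.finite(c)), all(is.finite(h)))
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  if (any(c < 0 | c > 1)) stop("'c' must lie in [0, 1]")
  if (any(h < 0 | h > 1)) stop("'h' must lie in [0, 1]")
  num <- c * h * (p - 1) - c * p + p
  den <- c * (h - 1) * (p - 1) + p
  if (any(abs(den) < 1e-12)) {
    stop("degenerate query: the threshold denominator vanishes")
  }
  out <- num / den
  # with no linked cost the ratio is p/p: pin it to 1 exactly
  out[rep_len(c == 0, length(out))] <- 1
  out
}

#' Can a cost-linked driver invade at a given inbreeding level?
#'
#' @inheritParams critical_inbreeding
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @return Logical: `TRUE` iff `F < critical_inbreeding(p, c, h)` (strict).
#' @export
can_invade <- function(p, c, h, F) {
  stopifnot(is.numeric(F), all(is.finite(F)))
  if (any(F < 0 | F > 1)) stop("'F' must lie in [0, 1]")
  F < critical_inbreeding(p, c, h)
}

#' Minimum initial frequency from which a cost-linked driver spreads
#'
#' Finds, by bisection on the sign of the one-generation change
#' [delta_p()], the smallest frequency at which a driver with linked cost
#' `c` (dominance `h`) gains ground under inbreeding `F` and transmission
#' bias `k`. Genotype fitnesses are `w11 = 1 - c`, `w12 = (1 - c h)/(2k)`,
#' `w22 = 1`.
#'
#' @param c,h Linked cost and dominance, each in `[0, 1]`.
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @param k Transmission bias in `(0.5, 1]`; default 1 (complete drive).
#' @param tol Absolute precision of the returned frequency (default `1e-6`).
#' @param max_iter Bisection iteration cap (default 200).
#' @param grid_n Number of points in the initial sign scan (default 1001).
#' @return The smallest invading frequency (0 if every positive frequency
#'   invades, to within `tol`), or `NA_real_` if no frequency in `(0, 1)`
#'   invades.
#' @examples
#' min_invasion_freq(c = 0.234, h = 0.083, F = 0.5)
#' @export
min_invasion_freq <- function(c, h, F, k = 1, tol = 1e-6, max_iter = 200L,
                              grid_n = 1001L) {
  stopifnot(length(c) == 1L, length(h) == 1L, length(F) == 1L, length(k) == 1L,
            tol > 0, grid_n >= 3L)
  if (c < 0 || c > 1) stop("'c' must lie in [0, 1]")
  if (h < 0 || h > 1) stop("'h' must lie in [0, 1]")
  if (F < 0 || F > 1) stop("'F' must lie in [0, 1]")
  if (k <= 0.5 || k > 1) stop("'k' must lie in (0.5, 1]")
  w <- fitness_from_costs(c, h, k = k, driver_linked_to_costly = TRUE)
  if (all(w == 0)) return(NA_real_)
  pars <- drive_params(k = k, w11 = w[["w11"]], w12 = w[["w12"]],
                       w22 = w[["w22"]], F = F)
  dp <- function(p) delta_p(p, pars)
  if (dp(tol) > 0) return(0)
  grid <- seq(tol, 1 - tol, length.out = grid_n)
  sgn <- dp(grid) > 0
  idx <- which(sgn)[1L]
  if (is.na(idx)) return(NA_real_)
  lo <- grid[idx - 1L]  # delta_p <= 0
  hi <- grid[idx]       # delta_p > 0
  iter <- 0L
  while (hi - lo > tol) {
    iter <- iter + 1L
    if (iter > max_iter) stop("bisection did not converge within ", max_iter,
                              " iterations")
    mid <- (lo + hi) / 2
    if (dp(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Grid of critical inbreeding coefficients
#'
#' Convenience wrapper evaluating [critical_inbreeding()] over the Cartesian
#' product of its arguments, e.g. for plotting invasion surfaces.
#'
#' @inheritParams critical_inbreeding
#' @return Data frame with columns `p`, `c`, `h`, `F_critical`.
#' @export
invasion_grid <- function(p, c, h) {
  g <- expand.grid(p = p, c = c, h = h, KEEP.OUT.ATTRS = FALSE)
  g$F_critical <- critical_inbreeding(g$p, g$c, g$h)
  g
}
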