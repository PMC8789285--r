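#' Zygote genotype counts from a two-fluorophore cross
#'
#' Counts of mated units (zygotes and asci) classified by fluorescence into
#' homozygotes for parent 1, heterozygotes, and homozygotes for parent 2,
#' together with the pre-mating frequency of parent 1. Free spores are not
#' genotyped by the microscopy assay and are not part of this table.
#'
#' @param n_hom1,n_het,n_hom2 Non-negative integer counts.
#' @param p_initial Pre-mating frequency of parent 1, in `[0, 1]`.
#' @return An object of class `zygote_counts`.
#' @examples
#' zygote_counts(30, 10, 0, p_initial = 0.5)
#' @export
zygote_counts <- function(n_hom1, n_het, n_hom2, p_initial) {
  stopifnot(length(n_hom1) == 1L, length(n_het) == 1L, length(n_hom2) == 1L,
            length(p_initial) == 1L,
            n_hom1 >= 0, n_het >= 0, n_hom2 >= 0,
            is.finite(p_initial), p_initial >= 0, p_initial <= 1)
  structure(list(n_hom1 = as.integer(n_hom1), n_het = as.integer(n_het),
                 n_hom2 = as.integer(n_hom2), p_initial = p_initial),
            class = "zygote_counts")
}

#' @export
print.zygote_counts <- function(x, ...) {
  cat(sprintf("Zygote/ascus genotype counts: hom1 %d, het %d, hom2 %d (p_initial = %.3g)\n",
              x$n_hom1, x$n_het, x$n_hom2, x$p_initial))
  invisible(x)
}

#' Inbreeding coefficient from zygote genotype counts
#'
#' The microscopy estimator `F = 1 - observed/expected` heterozygote
#' frequency, where the expectation is the Hardy-Weinberg value
#' `2 p (1 - p)` at the pre-mating parental frequency `p`. `F = 1` when no
#' heterozygous mated cells are seen; negative values indicate an excess of
#' outcrossing over random mating.
#'
#' @param counts A [zygote_counts()] object with a positive total and
#'   `p_initial` strictly inside `(0, 1)`.
#' @param reestimate_p Estimate the allele frequency from the zygote table
#'   itself (`p = (2 n_hom1 + n_het) / (2 total)`) instead of using
#'   `p_initial`. Default `FALSE`: the pre-mating census is the assay-grade
#'   denominator; re-estimation is intended for synthetic studies.
#' @return The estimated inbreeding coefficient (`<= 1`, possibly negative).
#' @examples
#' inbreeding_from_zygotes(zygote_counts(30, 10, 0, p_initial = 0.5)) # 0.5
#' @export
inbreeding_from_zygotes <- function(counts, reestimate_p = FALSE) {
  stopifnot(inherits(counts, "zygote_counts"))
  total <- counts$n_hom1 + counts$n_het + counts$n_hom2
  if (total == 0L) stop("empty data: no mated cells counted")
  p <- if (reestimate_p) {
    (2 * counts$n_hom1 + counts$n_het) / (2 * total)
  } else {
    counts$p_initial
  }
  if (p <= 0 || p >= 1) {
    stop("the expected heterozygote frequency is undefined at p = ", p)
  }
  het_obs <- counts$n_het / total
  1 - het_obs / (2 * p * (1 - p))
}

#' Mating efficiency from a cell census
#'
#' Percentage of cells that entered mating, computed from microscopy counts
#' of vegetative cells (`V`), zygotes (`Z`), asci (`A`) and free spores
#' (`S`):
#' \deqn{ME\% = \frac{2Z + 2A + S/2}{wV + 2Z + 2A + S/2} \times 100,}
#' with vegetative weight `w = 2` by default. Mated units count the two
#' cells that formed them and each free spore counts half a cell (four
#' spores arise from a two-cell mating).
#'
#' @param V,Z,A,S Non-negative counts of vegetative cells, zygotes, asci and
#'   free spores; not all zero.
#' @param vegetative_weight Weight applied to `V` in the denominator
#'   (default 2; use 1 for strict per-cell accounting).
#' @return Mating efficiency as a percentage in `[0, 100]`.
#' @examples
#' mating_efficiency(V = 2, Z = 1, A = 1, S = 2) # 55.56
#' @export
mating_efficiency <- function(V, Z, A, S, vegetative_weight = 2) {
  stopifnot(length(V) == 1L, length(Z) == 1L, length(A) == 1L, length(S) == 1L,
            V >= 0, Z >= 0, A >= 0, S >= 0, vegetative_weight > 0)
  mated <- 2 * Z + 2 * A + S / 2
  denom <- vegetative_weight * V + mated
  if (denom == 0) stop("empty data: all census counts are zero")
  100 * mated / denom
}

#' Correct a recombinant fraction for undetectable outcross progeny
#'
#' With `n` unlinked markers segregating in a cross, a heterozygous (i.e.
#' outcrossed) diploid produces the `2^n` multilocus genotypes in equal
#' frequency, of which 2 are the parental types and thus indistinguishable
#' from inbred progeny. The observed recombinant fraction therefore
#' underestimates the outcross fraction by the factor `(2^n - 2) / 2^n`
#' (6/8 for three markers, 2/4 for two), and this function divides it out.
#'
#' @param recombinant_fraction Observed fraction of recombinant progeny, in
#'   `[0, 1]`.
#' @param n_markers Number of unlinked segregating markers (>= 2).
#' @return The corrected outcross fraction; values that overshoot 1 through
#'   sampling noise are capped at 1 with a warning.
#' @examples
#' outcross_from_recombinants(0.375, n_markers = 3) # 0.5
#' @export
outcross_from_recombinants <- function(recombinant_fraction, n_markers) {
  stopifnot(length(recombinant_fraction) == 1L, length(n_markers) == 1L,
            is.finite(recombinant_fraction),
            recombinant_fraction >= 0, recombinant_fraction <= 1)
  if (n_markers < 2 || n_markers != as.integer(n_markers)) {
    stop("'n_markers' must be an integer >= 2 (no recombinants are observable otherwise)")
  }
  share <- (2^n_markers - 2) / 2^n_markers
  out <- recombinant_fraction / share
  if (out > 1) {
    warning("corrected outcross fraction ", signif(out, 4),
            " exceeds 1 (sampling noise); capped at 1")
    out <- 1
  }
  out
}

#' Inbreeding coefficient from recombinant progeny genotypes
#'
#' The genetic estimator: the observed recombinant fraction is corrected to
#' a true outcross fraction with [outcross_from_recombinants()], then
#' `F = 1 - outcross / (2 p (1 - p))`, the Hardy-Weinberg expected
#' heterozygosity at the parental mixing frequency `p`.
#'
#' @inheritParams outcross_from_recombinants
#' @param p Initial frequency of parent 1 in the cross, strictly in `(0, 1)`.
#' @return The estimated inbreeding coefficient (`<= 1`).
#' @examples
#' inbreeding_from_genetic(0.125, n_markers = 2, p = 0.5) # 0.5
#' @export
inbreeding_from_genetic <- function(recombinant_fraction, n_markers, p) {
  stopifnot(length(p) == 1L, is.finite(p))
  if (p <= 0 || p >= 1) stop("'p' must lie strictly in (0, 1)")
  outcross <- outcross_from_recombinants(recombinant_fraction, n_markers)
  1 - outcross / (2 * p * (1 - p))
}

#' Observed recombinant fraction of a progeny genotype table
#'
#' Fraction of progeny whose multilocus genotype differs from both parental
#' genotypes stored with the table (see [sim_progeny_table()]).
#'
#' @param progeny A data frame of marker genotypes, one row per progeny, one
#'   column per marker, values coded 1/2 for parental origin, with
#'   `parental_genotypes` attribute.
#' @return Fraction of recombinant progeny in `[0, 1]`.
#' @export
recombinant_fraction <- function(progeny) {
  stopifnot(is.data.frame(progeny), nrow(progeny) > 0)
  parents <- attr(progeny, "parental_genotypes")
  if (is.null(parents)) {
    n <- ncol(progeny)
    parents <- list(rep(1L, n), rep(2L, n))
  }
  m <- as.matrix(progeny)
  is_parental <- apply(m, 1L, function(g) {
    all(g == parents[[1L]]) || all(g == parents[[2L]])
  })
  mean(!is_parental)
}

#' Expected zygote genotype frequencies in a mixed-isolate cross
#'
#' Additive model for a cross between two isolates with their own
#' (isogenic-cross) inbreeding coefficients `F1`, `F2` and mating
#' efficiencies `me1`, `me2` (unmated fractions `u_i = 1 - me_i`), mixed at
#' initial frequency `p` of strain 1. Each strain is assumed to contribute
#' to the cross as it would to its own, without adjusting to the partner:
#' \deqn{hom_1 = [p^2 + p(1-p)F_1](1-u_1)}
#' \deqn{het = 2p(1-p)\left[1-\tfrac{F_1+F_2}{2}\right]\left[1-\tfrac{u_1+u_2}{2}\right]}
#' and `hom2` is the remainder.
#'
#' @param p Initial frequency of strain 1, in `[0, 1]`.
#' @param F1,F2 Isogenic-cross inbreeding coefficients, in `[0, 1]`.
#' @param me1,me2 Mating efficiencies as fractions in `[0, 1]`.
#' @return Named numeric vector `c(hom1, het, hom2)` summing to 1.
#' @examples
#' expected_mixed_cross(0.5, F1 = 0.5, F2 = 0, me1 = 0.4, me2 = 0.5)
#' @export
expected_mixed_cross <- function(p, F1, F2, me1, me2) {
  for (nm in c("p", "F1", "F2", "me1", "me2")) {
    v <- get(nm)
    stopifnot(length(v) == 1L, is.finite(v))
    if (v < 0 || v > 1) stop(sprintf("'%s' must lie in [0, 1]", nm))
  }
  u1 <- 1 - me1
  u2 <- 1 - me2
  hom1 <- (p^2 + p * (1 - p) * F1) * (1 - u1)
  het <- 2 * p * (1 - p) * (1 - (F1 + F2) / 2) * (1 - (u1 + u2) / 2)
  hom2 <- 1 - hom1 - het
  if (hom2 < 0) {
    stop("inconsistent parameters: the implied strain-2 homozygote frequency is negative")
  }
  c(hom1 = hom1, het = het, hom2 = hom2)
}

#' Percentile bootstrap confidence interval for a count-data estimator
#'
#' Multinomial resampling of a [zygote_counts()] table: each bootstrap
#' replicate redraws the three genotype counts at the observed proportions
#' and total, re-applies `statistic`, and the interval is taken from the
#' percentiles of the resulting distribution. Degenerate resamples on which
#' the statistic errors out (e.g. an empty category making the estimator
#' undefined) are skipped and counted.
#'
#' @param counts A [zygote_counts()] object.
#' @param statistic Function of a `zygote_counts` object returning a scalar;
#'   default [inbreeding_from_zygotes()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param conf Two-sided confidence level (default 0.95).
#' @param seed RNG seed (optional); the caller's RNG state is preserved.
#' @return A list with `estimate`, `lower`, `upper`, `n_boot`, `n_skipped`,
#'   `conf`, and `seed`.
#' @examples
#' bootstrap_ci(zygote_counts(300, 100, 200, 0.5), n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(counts, statistic = inbreeding_from_zygotes,
                         n_boot = 1000L, conf = 0.95, seed = NULL) {
  stopifnot(inherits(counts, "zygote_counts"), is.function(statistic),
            conf > 0, conf < 1)
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  total <- counts$n_hom1 + counts$n_het + counts$n_hom2
  if (total == 0L) stop("empty data: no mated cells counted")
  probs <- c(counts$n_hom1, counts$n_het, counts$n_hom2) / total
  est <- statistic(counts)
  with_seed(seed, {
    draws <- stats::rmultinom(n_boot, total, probs)
    vals <- apply(draws, 2L, function(x) {
      tryCatch(statistic(zygote_counts(x[1L], x[2L], x[3L], counts$p_initial)),
               error = function(e) NA_real_)
    })
    ok <- vals[is.finite(vals)]
    if (length(ok) == 0L) stop("all bootstrap resamples were degenerate")
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(estimate = est, lower = qs[1L], upper = qs[2L],
         n_boot = length(ok), n_skipped = n_boot - length(ok),
         conf = conf, seed = seed)
  })
}
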